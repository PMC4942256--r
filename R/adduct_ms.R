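# Monoisotopic masses of the most abundant isotopes (IUPAC/CODATA), Da.
.isotope_mass <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151, S = 31.97207069)
.water_mass <- 18.0105646859
.proton_mass <- 1.00727646688

#' Parse a Hill-notation molecular formula
#'
#' @param formula string such as \code{"C25H36O4"}; elements restricted to
#'   C, H, N, O, P, S.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula))
    stop("malformed formula: ", formula, call. = FALSE)
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(ifelse(grepl("[0-9]+$", toks),
                         sub("^[A-Za-z]+", "", toks), "1"))
  bad <- setdiff(el, names(.isotope_mass))
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  counts <- tapply(n, factor(el, levels = unique(el)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Monoisotopic (exact) mass of a molecular formula
#'
#' Sum of most-abundant-isotope atomic masses; full precision is kept
#' internally and rounding happens only at presentation.
#'
#' @param formula Hill-notation string or named count vector.
#' @return mass in Da.
#' @examples
#' monoisotopic_mass("C25H36O4")  # ophiobolin A, 400.2614 at 4 d.p.
#' monoisotopic_mass("C2H7NO")    # ethanolamine, 61.0528 at 4 d.p.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (!length(counts)) stop("empty formula", call. = FALSE)
  sum(.isotope_mass[names(counts)] * counts)
}

#' A molecule defined by formula or fixed monoisotopic mass
#'
#' @param name display name.
#' @param formula Hill-notation formula (optional if \code{mass} given).
#' @param mass fixed monoisotopic mass in Da (overrides nothing: exactly one
#'   of \code{formula}/\code{mass} must be supplied).
#' @return object of class \code{molecule} with fields name, formula, mass.
#' @export
molecule <- function(name, formula = NULL, mass = NULL) {
  if (is.null(formula) == is.null(mass))
    stop("supply exactly one of formula or mass", call. = FALSE)
  m <- if (is.null(mass)) monoisotopic_mass(formula) else mass
  if (m <= 0) stop("mass must be positive", call. = FALSE)
  structure(list(name = name, formula = formula, mass = m),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("%s%s: monoisotopic mass %.4f Da\n", x$name,
              if (!is.null(x$formula)) paste0(" (", x$formula, ")") else "",
              x$mass))
  invisible(x)
}

as_mass <- function(x) {
  if (inherits(x, "molecule")) x$mass
  else if (is.numeric(x)) x
  else monoisotopic_mass(x)
}

#' Paal-Knorr adduct mass of a 1,4-dicarbonyl with a primary amine
#'
#' Condensation of a 1,4-dicarbonyl (e.g. ophiobolin A) with a primary amine
#' (e.g. the ethanolamine head group of PE) forms a pyrrole, losing two
#' waters: adduct mass = parent + amine - 2 x H2O.
#'
#' @param carbonyl_parent \code{molecule}, formula string, or mass in Da.
#' @param primary_amine \code{molecule}, formula string, or mass in Da.
#' @return neutral adduct monoisotopic mass in Da.
#' @examples
#' paal_knorr_adduct_mass("C25H36O4", "C2H7NO")  # Etn-OPA, 425.2930 at 4 d.p.
#' @export
paal_knorr_adduct_mass <- function(carbonyl_parent, primary_amine) {
  as_mass(carbonyl_parent) + as_mass(primary_amine) - 2 * .water_mass
}

#' m/z of a protonated ion
#'
#' \code{[M + zH]^(z+)}: (neutral mass + z protons) / z.
#'
#' @param neutral_mass neutral monoisotopic mass in Da (> 0).
#' @param charge positive integer charge (default 1).
#' @return m/z.
#' @export
protonated_mz <- function(neutral_mass, charge = 1L) {
  if (any(neutral_mass <= 0)) stop("neutral mass must be > 0", call. = FALSE)
  if (any(charge < 1)) stop("charge must be >= 1", call. = FALSE)
  (neutral_mass + charge * .proton_mass) / charge
}

# half-up rounding at k decimals, matching printed-precision conventions
round_half_up <- function(x, k = 4L) floor(x * 10^k + 0.5) / 10^k

#' Extracted-ion-chromatogram m/z window at a ppm half-width
#'
#' The center is first rounded half-up at 4 decimals (the precision at which
#' instrument software displays m/z), then widened by \code{center * ppm *
#' 1e-6} on each side, each bound again rounded at 4 decimals.
#'
#' @param center m/z of the target ion.
#' @param ppm relative half-width in parts per million (default 5).
#' @return object of class \code{mz_window}: list(low, high, center, ppm).
#' @examples
#' eic_window(protonated_mz(paal_knorr_adduct_mass("C25H36O4", "C2H7NO")))
#' @export
eic_window <- function(center, ppm = 5) {
  if (center <= 0) stop("center must be > 0", call. = FALSE)
  if (ppm < 0) stop("ppm must be >= 0", call. = FALSE)
  c0 <- round_half_up(center, 4L)
  w <- structure(list(low = round_half_up(c0 * (1 - ppm * 1e-6), 4L),
                      high = round_half_up(c0 * (1 + ppm * 1e-6), 4L),
                      center = c0, ppm = ppm),
                 class = "mz_window")
  w
}

#' @export
print.mz_window <- function(x, ...) {
  cat(sprintf("m/z window %.4f-%.4f (center %.4f, +/- %g ppm)\n",
              x$low, x$high, x$center, x$ppm))
  invisible(x)
}

#' Adduct m/z report for a carbonyl parent and a primary amine
#'
#' One-call summary used for planning EIC extraction: neutral Paal-Knorr
#' adduct mass, protonated m/z, and the ppm window bounds.
#'
#' @inheritParams paal_knorr_adduct_mass
#' @param ppm window half-width (default 5).
#' @return data.frame: neutral, mz_protonated, low, high.
#' @export
adduct_mz_report <- function(carbonyl_parent, primary_amine, ppm = 5) {
  neutral <- paal_knorr_adduct_mass(carbonyl_parent, primary_amine)
  mz <- protonated_mz(neutral)
  w <- eic_window(mz, ppm)
  data.frame(neutral = round_half_up(neutral, 4L),
             mz_protonated = w$center, low = w$low, high = w$high)
}
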