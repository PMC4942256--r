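#' PE fraction from phosphorus analysis
#'
#' Total phospholipid phosphate is split chromatographically into a PE
#' fraction and an everything-else fraction; the PE content is the inorganic
#' phosphate recovered in the PE tube over the sum of both tubes.
#'
#' @param pi_pe phosphate quantity in the PE tube (nmol, >= 0).
#' @param pi_other phosphate quantity in the tube containing all other
#'   phospholipids (nmol, >= 0).
#' @return fraction in [0, 1].
#' @export
pe_fraction <- function(pi_pe, pi_other) {
  if (any(pi_pe < 0 | pi_other < 0))
    stop("phosphate quantities must be non-negative", call. = FALSE)
  if (any(pi_pe + pi_other == 0))
    stop("both phosphate quantities are zero", call. = FALSE)
  pi_pe / (pi_pe + pi_other)
}

#' Radiolabel flux normalized to total phospholipid
#'
#' 14C counts incorporated into PE divided by total phospholipid phosphate;
#' optionally expressed relative to a vehicle-treated sample.
#'
#' @param cpm_pe scintillation counts per minute in the PE fraction.
#' @param total_pi total phospholipid phosphate (nmol, > 0).
#' @param vehicle optional numeric: the same ratio for the vehicle control;
#'   if given, the vehicle-relative flux (ratio of ratios) is returned.
#' @return cpm per nmol phospholipid, or the unitless vehicle-relative flux.
#' @export
c14_flux <- function(cpm_pe, total_pi, vehicle = NULL) {
  if (any(total_pi <= 0))
    stop("total phospholipid must be positive", call. = FALSE)
  r <- cpm_pe / total_pi
  if (is.null(vehicle)) r else r / vehicle
}

#' Calcein leakage percentage
#'
#' Fluorescence is normalized between a vehicle-treated liposome series (0%
#' leakage) and a detergent-lysed series (100% leakage), per time point.
#' Inputs are assumed background-subtracted per condition. Values outside
#' [0, 100] (instrument noise under/overshooting the references) are reported
#' as-is with an out-of-range flag, not clipped.
#'
#' @param f fluorescence of the treated sample (a.u.), one value per time
#'   point.
#' @param f_vehicle vehicle (0%) reference series, same length.
#' @param f_triton detergent (100%) reference series, same length.
#' @return data.frame: percent, out_of_range.
#' @export
leakage_percent <- function(f, f_vehicle, f_triton) {
  if (length(f) != length(f_vehicle) || length(f) != length(f_triton))
    stop("fluorescence series must have equal length", call. = FALSE)
  if (any(f_triton == f_vehicle))
    stop("0% and 100% references coincide at some time point", call. = FALSE)
  pct <- 100 * (f - f_vehicle) / (f_triton - f_vehicle)
  data.frame(percent = pct, out_of_range = pct < 0 | pct > 100)
}

#' Viability relative to a vehicle-treated control
#'
#' @param signal luminescence of the treated sample (a.u.).
#' @param vehicle_signal luminescence of the vehicle control (> 0).
#' @return unitless ratio (vehicle maps to 1).
#' @export
relative_viability <- function(signal, vehicle_signal) {
  if (any(vehicle_signal <= 0))
    stop("vehicle signal must be positive", call. = FALSE)
  signal / vehicle_signal
}

#' Relative expression by the delta-delta-CT method
#'
#' For each primer pair, \eqn{\Delta CT = CT_{target} - CT_{reference}}
#' (reference gene e.g. GAPDH), averaged over replicates;
#' \eqn{\Delta\Delta CT = \Delta CT_{test} - \Delta CT_{calibrator}} and the
#' fold change is \eqn{2^{-\Delta\Delta CT}} (standard sign convention: an
#' expression increase in the test sample gives a negative
#' \eqn{\Delta\Delta CT} and a fold change above 1). The per-pair values are
#' averaged; \code{fold_magnitude} (\eqn{2^{|mean \Delta\Delta CT|}}) is also
#' reported for comparison with magnitude-style presentations.
#'
#' @param test data.frame for the test sample: columns \code{primer},
#'   \code{ct_target}, \code{ct_ref}; replicate rows allowed.
#' @param calibrator same layout for the calibrator sample; must carry the
#'   same primer pairs.
#' @return list: \code{per_primer} (primer, ddct, fold), \code{mean_ddct},
#'   \code{fold_change} (\eqn{2^{-mean}}), \code{fold_magnitude}.
#' @export
ddct_relative_expression <- function(test, calibrator) {
  check_ct <- function(x, nm) {
    stopifnot(all(c("primer", "ct_target", "ct_ref") %in% names(x)))
    if (any(x$ct_target <= 0 | x$ct_target >= 45 |
            x$ct_ref <= 0 | x$ct_ref >= 45))
      stop("CT values in ", nm, " outside (0, 45)", call. = FALSE)
  }
  check_ct(test, "test"); check_ct(calibrator, "calibrator")
  if (!setequal(test$primer, calibrator$primer))
    stop("test and calibrator use different primer pairs", call. = FALSE)
  dct <- function(x) {
    vapply(split(x, x$primer),
           function(g) mean(g$ct_target) - mean(g$ct_ref), numeric(1))
  }
  d_test <- dct(test)
  d_cal <- dct(calibrator)[names(d_test)]
  ddct <- d_test - d_cal
  per <- data.frame(primer = names(ddct), ddct = as.numeric(ddct),
                    fold = 2^-as.numeric(ddct), stringsAsFactors = FALSE)
  rownames(per) <- NULL
  m <- mean(per$ddct)
  list(per_primer = per, mean_ddct = m, fold_change = 2^-m,
       fold_magnitude = 2^abs(m))
}
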