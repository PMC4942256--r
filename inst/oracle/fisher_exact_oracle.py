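"""Exact-rational upper-tail hypergeometric enumeration.

Enumerates every 2x2 table [[x, n1 - x], [k - x, n2 - (k - x)]] with both row
margins n1, n2 between 1 and a maximum M, and writes the one-sided
(enrichment) Fisher p-value P(X >= x) computed in exact integer arithmetic
(math.comb; the division to a float is the only rounding step).

Usage: python fisher_exact_oracle.py M OUT_TSV
Output columns: n1 n2 k x p
"""
import sys
from math import comb


def main(max_margin: int, out_path: str) -> None:
    with open(out_path, "w") as fh:
        fh.write("n1\tn2\tk\tx\tp\n")
        for n1 in range(1, max_margin + 1):
            for n2 in range(1, max_margin + 1):
                denom_n = n1 + n2
                for k in range(0, n1 + n2 + 1):
                    lo = max(0, k - n2)
                    hi = min(n1, k)
                    coeffs = [comb(n1, x) * comb(n2, k - x)
                              for x in range(lo, hi + 1)]
                    denom = comb(denom_n, k)  # == sum(coeffs)
                    # suffix sums give the exact upper-tail numerators
                    tail = 0
                    tails = [0] * len(coeffs)
                    for i in range(len(coeffs) - 1, -1, -1):
                        tail += coeffs[i]
                        tails[i] = tail
                    for i, x in enumerate(range(lo, hi + 1)):
                        p = tails[i] / denom
                        fh.write(f"{n1}\t{n2}\t{k}\t{x}\t{p!r}\n")


if __name__ == "__main__":
    main(int(sys.argv[1]), sys.argv[2])
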