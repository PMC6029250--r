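# The nine binary similarity coefficients over the (a, b, c, d) contingency
# of two bit vectors: a = set in both, b = first only, c = second only,
# d = unset in both, n = a + b + c + d.

MEASURES <- c("tanimoto", "dice", "ochiai", "simpson", "russell_rao",
              "sokal_michener", "faith", "gower_legendre", "rogers_tanimoto")

#' Bit-contingency counts of two fingerprints
#'
#' @param fpA,fpB two `rs_fp` of equal type and length.
#' @return an `rs_bitcounts` list with fields `a`, `b`, `c`, `d`, `n`.
#' @export
bit_counts <- function(fpA, fpB) {
  if (!inherits(fpA, "rs_fp") || !inherits(fpB, "rs_fp"))
    rs_error("bit_counts expects two rs_fp objects", "rs_incompat_error")
  if (fpA$length != fpB$length || fpA$fp_type != fpB$fp_type)
    rs_error(sprintf("incompatible fingerprints: %s/%d vs %s/%d",
                     fpA$fp_type, fpA$length, fpB$fp_type, fpB$length),
             "rs_incompat_error")
  a <- sum(fpA$bits & fpB$bits)
  b <- sum(fpA$bits & !fpB$bits)
  c <- sum(!fpA$bits & fpB$bits)
  structure(list(a = a, b = b, c = c, d = fpA$length - a - b - c,
                 n = fpA$length), class = "rs_bitcounts")
}

new_bit_counts <- function(a, b, c, d) {
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d),
            class = "rs_bitcounts")
}

#' Binary similarity coefficient from bit counts
#'
#' Implements the nine coefficients (plus the audit variant
#' `tanimoto_printed`, see Details).  When a coefficient's denominator is
#' zero the convention is: 1 if the two underlying vectors are identical
#' (b == c == 0), else 0.
#'
#' @details `tanimoto` is the standard a/(a+b+c).  `tanimoto_printed` is the
#' asymmetric variant a/((a+b)+(a+c)-c) = a/(2a+b) that results from a
#' typesetting slip in the original definition table; it is exposed for
#' auditability only and is not part of the nine selectable measures.
#'
#' @param counts an `rs_bitcounts` (or list with fields a, b, c, d).
#' @param measure one of `measure_names()`, or `"tanimoto_printed"`.
#' @return similarity in `[0, 1]`.
#' @export
similarity <- function(counts, measure = "tanimoto") {
  if (!measure %in% c(MEASURES, "tanimoto_printed"))
    rs_error(sprintf("unknown measure '%s'; valid measures: %s", measure,
                     paste(MEASURES, collapse = ", ")), "rs_enum_error")
  a <- counts$a; b <- counts$b; c <- counts$c; d <- counts$d
  n <- a + b + c + d
  # identity convention: identical vectors (b == c == 0) score 1 under every
  # measure, including the asymptotic ones (russell_rao, faith) whose raw
  # formulas would give a/n < 1 on self-comparison
  if (b == 0 && c == 0) return(1)
  frac <- function(num, den) if (den == 0) 0 else num / den
  switch(measure,
         tanimoto = frac(a, a + b + c),
         tanimoto_printed = frac(a, 2 * a + b),
         dice = frac(2 * a, 2 * a + b + c),
         ochiai = frac(a, sqrt(a + b) * sqrt(a + c)),
         simpson = frac(a, min(a + b, a + c)),
         russell_rao = frac(a, n),
         sokal_michener = frac(a + d, n),
         faith = frac(a + 0.5 * d, n),
         gower_legendre = frac(a + d, a + 0.5 * (b + c) + d),
         rogers_tanimoto = frac(a + d, a + 2 * (b + c) + d))
}

#' Names of the nine selectable similarity measures
#' @return character vector of length 9; the default measure is
#'   `"tanimoto"`.
#' @export
measure_names <- function() MEASURES

#' Names of the four fingerprint types
#' @return character vector of length 4.
#' @export
fingerprint_types <- function() FP_TYPES

#' Fingerprint similarity of two molecules
#'
#' @param molA,molB `rs_mol` objects.
#' @param fp_type fingerprint type.
#' @param measure similarity measure.
#' @return similarity in `[0, 1]`.
#' @export
molecule_similarity <- function(molA, molB, fp_type = "extended",
                                measure = "tanimoto") {
  similarity(bit_counts(fingerprint(molA, fp_type), fingerprint(molB, fp_type)),
             measure)
}
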