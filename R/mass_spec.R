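# Monoisotopic masses of the elements the formula parser accepts
# (CODATA/IUPAC values, most abundant isotope).
MONO_MASS <- c(
  C = 12.0, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  S = 31.97207069, P = 30.97376151, Na = 22.98976928, K = 38.9637069,
  Cl = 34.96885271, Br = 78.9183376, F = 18.99840320, I = 126.904468,
  Fe = 55.9349421, Se = 73.9224766, Si = 27.9769265
)

PROTON_MASS <- 1.0072765    # mass of H minus one electron

parse_formula <- function(formula) {
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (paste(parts, collapse = "") != formula)
    stopf("cannot parse formula '%s'", formula)
  el <- sub("[0-9]*$", "", parts)
  n <- as.integer(sub("^[A-Za-z]+", "", parts))
  n[is.na(n)] <- 1L
  unknown <- setdiff(el, names(MONO_MASS))
  if (length(unknown)) stopf("unknown element(s): %s",
                             paste(unknown, collapse = ", "))
  stats::setNames(n, el)
}

#' Monoisotopic mass of an elemental formula
#' @param formula e.g. `"C25H48N6O8"`.
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(MONO_MASS[names(counts)] * counts)
}

ADDUCTS <- list(
  "[M+H]+"   = list(n_h = 1,  z = 1, extra = 0,                 polarity = "+"),
  "[M+2H]2+" = list(n_h = 2,  z = 2, extra = 0,                 polarity = "+"),
  "[M+Na]+"  = list(n_h = 0,  z = 1, extra = 22.98976928 - 5.48579909e-4,
                    polarity = "+"),
  "[M-H]-"   = list(n_h = -1, z = 1, extra = 0,                 polarity = "-")
)

normalize_adduct <- function(adduct) {
  a <- gsub("−|–", "-", adduct)   # unicode minus/dash
  gsub("\\s+", "", a)
}

#' m/z of a named adduct of a molecular formula
#'
#' Computes the monoisotopic mass from the built-in element table and
#' forms the ion: `(M + n * m_proton) / n` for `[M+nH]n+`, `M - m_proton`
#' for `[M-H]-`, and `M + m(Na+)` for `[M+Na]+`. The result is rounded
#' half-even to 3 decimals, the precision at which target ions are
#' reported.
#'
#' @param formula elemental formula, e.g. `"C25H48N6O8"` (DFO-B).
#' @param adduct one of `"[M+H]+"`, `"[M+2H]2+"`, `"[M+Na]+"`, `"[M-H]-"`.
#' @param digits decimals to round to (half-even); `Inf` for unrounded.
#' @return m/z rounded to `digits` decimals.
#' @examples
#' adduct_mz("C25H48N6O8", "[M+2H]2+")  # 281.184, the DFO-B target ion
#' adduct_mz("H2O", "[M+H]+")           # 19.018
#' @export
adduct_mz <- function(formula, adduct, digits = 3) {
  a <- ADDUCTS[[normalize_adduct(adduct)]]
  if (is.null(a)) stopf("unsupported adduct '%s' (supported: %s)", adduct,
                        paste(names(ADDUCTS), collapse = ", "))
  M <- monoisotopic_mass(formula)
  mz <- (M + a$n_h * PROTON_MASS + a$extra) / a$z
  if (is.finite(digits)) round(mz, digits) else mz
}

#' Annotate peak-table features against known target ions
#'
#' A simple targeted matcher (a stand-in for probabilistic annotation):
#' feature f matches a target ion iff the relative mass error
#' `|mz_f - mz_target| / mz_target * 1e6` is within `tol_ppm` and the
#' feature's polarity agrees with the adduct's.
#'
#' @param table a [peak_table()].
#' @param targets data frame with columns name, formula, and optionally
#'   adducts (semicolon-separated list; defaults to all supported).
#' @param tol_ppm mass tolerance in parts per million (> 0).
#' @return data frame: feature_id, mz, name, adduct, target_mz, ppm_error.
#' @export
match_known_ions <- function(table, targets, tol_ppm = 10) {
  if (tol_ppm <= 0) stopf("tol_ppm must be > 0")
  out <- list()
  for (i in seq_len(nrow(targets))) {
    adds <- if (!is.null(targets$adducts))
      strsplit(targets$adducts[i], ";")[[1]] else names(ADDUCTS)
    for (ad in adds) {
      ad <- normalize_adduct(ad)
      tmz <- adduct_mz(targets$formula[i], ad)
      pol <- ADDUCTS[[ad]]$polarity
      ppm <- (table$features$mz - tmz) / tmz * 1e6
      hit <- abs(ppm) <= tol_ppm & table$features$polarity == pol
      if (any(hit))
        out[[length(out) + 1L]] <- data.frame(
          feature_id = table$features$feature_id[hit],
          mz = table$features$mz[hit], name = targets$name[i],
          adduct = ad, target_mz = tmz, ppm_error = round(ppm[hit], 2),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(feature_id = character(), mz = numeric(),
                      name = character(), adduct = character(),
                      target_mz = numeric(), ppm_error = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
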