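#' Experimental design for a pairwise co-culture community
#'
#' Describes the full factorial layout the pipeline consumes: every ordered
#' (focal, partner) strain pair, sampled on a series of days with replicate
#' plates. Sample labels follow the fixed `"FOCAL-PARTNER"` convention
#' (e.g. `"A-C"` is strain A grown next to strain C), with day and
#' replicate suffixes: `"A-C_d4_r2"`.
#'
#' @param strains character vector of unique strain identifiers.
#' @param days integer vector of sampling days post inoculation.
#' @param replicates replicate plates per condition per day (>= 2; the
#'   downstream t-tests are undefined below that).
#' @param seed integer RNG seed recorded in the design and used by all
#'   generators that take the design as input.
#' @return An object of class `synth_design`: a list with the arguments and
#'   a `samples` data frame (sample_id, focal, partner, day, replicate).
#' @examples
#' d <- synth_design(strains = c("A", "C"), days = 2:3, replicates = 2)
#' nrow(d$samples)  # 2 strains x 2 partners x 2 days x 2 reps = 16
#' @export
synth_design <- function(strains = c("A", "B", "C", "D"), days = 2:6,
                         replicates = 3, seed = 1L) {
  if (length(strains) == 0L || anyDuplicated(strains) > 0L)
    stopf("strains must be non-empty and unique")
  if (replicates < 2L) stopf("replicates must be >= 2 (t-tests require it)")
  grid <- expand.grid(replicate = seq_len(replicates), day = as.integer(days),
                      partner = strains, focal = strains,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("focal", "partner", "day", "replicate")]
  grid$sample_id <- sprintf("%s-%s_d%d_r%d", grid$focal, grid$partner,
                            grid$day, grid$replicate)
  structure(list(strains = as.character(strains), days = as.integer(days),
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 samples = grid[, c("sample_id", "focal", "partner",
                                    "day", "replicate")]),
            class = "synth_design")
}

#' @export
print.synth_design <- function(x, ...) {
  cat(sprintf("synth_design: %d strains (%s), days %s, %d replicates, seed %d\n",
              length(x$strains), paste(x$strains, collapse = ","),
              paste(range(x$days), collapse = "-"), x$replicates, x$seed))
  cat(sprintf("  %d samples\n", nrow(x$samples)))
  invisible(x)
}

#' Planted ground truth for the synthetic experiment
#'
#' Collects the effects planted by the generators so parameter-recovery
#' tests can compare pipeline output against known truth.
#'
#' @param producer_features data frame with columns `feature_id`,
#'   `producer` (strain), `responder` (partner strain whose presence
#'   induces the feature, or NA for constitutive production), `lfc`
#'   (planted log2 effect, finite and nonzero), `diffusible` (logical:
#'   the compound also appears in the partner's paired sample).
#' @param de_genes data frame with columns `gene_id`, `strain`, `partner`,
#'   `day_min`, `day_max`, `lfc`.
#' @param colony_truth data frame with columns `image_id`, `cx`, `cy`,
#'   `radius`, `area_px` (true disk area), `overlapping` (logical).
#' @return An object of class `planted_truth`.
#' @export
planted_truth <- function(producer_features = NULL, de_genes = NULL,
                          colony_truth = NULL) {
  empty_pf <- data.frame(feature_id = character(), producer = character(),
                         responder = character(), lfc = numeric(),
                         diffusible = logical(), stringsAsFactors = FALSE)
  empty_de <- data.frame(gene_id = character(), strain = character(),
                         partner = character(), day_min = integer(),
                         day_max = integer(), lfc = numeric(),
                         stringsAsFactors = FALSE)
  pf <- producer_features %||% empty_pf
  de <- de_genes %||% empty_de
  if (nrow(pf) && (!all(is.finite(pf$lfc)) || any(pf$lfc == 0)))
    stopf("planted feature log2 effects must be finite and nonzero")
  if (nrow(de) && (!all(is.finite(de$lfc)) || any(de$lfc == 0)))
    stopf("planted DE log2 effects must be finite and nonzero")
  structure(list(producer_features = pf, de_genes = de,
                 colony_truth = colony_truth),
            class = "planted_truth")
}
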