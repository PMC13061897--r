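#' Median-of-ratios size factors
#'
#' Per sample j, the factor is the median over genes of
#' `K[i,j] / geomean_i` where `geomean_i` is the gene's geometric mean
#' across samples; genes with a zero anywhere (zero geometric mean) are
#' skipped, and genes never observed at all are dropped up front. With
#' `pseudo_reference = TRUE` the geometric mean is instead taken over the
#' positive counts only, a fallback for sparse matrices in which no gene
#' is observed in every sample.
#'
#' @param counts count matrix (genes x samples) or a `count_matrix`.
#' @param pseudo_reference use the positive-count geometric mean fallback.
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  K <- if (inherits(counts, "count_matrix")) counts$counts else counts
  K <- K[rowSums(K) > 0, , drop = FALSE]
  logK <- log(K)
  if (pseudo_reference) {
    logK[!is.finite(logK)] <- NA
    ref <- rowMeans(logK, na.rm = TRUE)
  } else {
    ref <- rowMeans(logK)
    if (!any(is.finite(ref)))
      stopf("no gene has a nonzero count in every sample; rerun with pseudo_reference = TRUE")
  }
  s <- apply(logK, 2, function(col) {
    r <- col - ref
    exp(stats::median(r[is.finite(r)]))
  })
  s
}

#' Counts normalized by median-of-ratios size factors
#' @inheritParams size_factors
#' @return matrix of normalized counts.
#' @export
normalized_counts <- function(counts, pseudo_reference = FALSE) {
  K <- if (inherits(counts, "count_matrix")) counts$counts else counts
  sweep(K, 2, size_factors(counts, pseudo_reference), "/")
}

#' Transcripts per million
#'
#' `TPM[i,j] = (K[i,j]/L_i) / sum_i(K[i,j]/L_i) * 1e6`. Columns with no
#' counts at all come back all-zero and are reported in
#' `attr(, "zero_columns")`.
#'
#' @param counts count matrix (genes x samples) or a `count_matrix`.
#' @param gene_lengths lengths in bp, named by gene (taken from the
#'   `count_matrix` if not given).
#' @return TPM matrix; every non-degenerate column sums to 1e6.
#' @export
tpm <- function(counts, gene_lengths = NULL) {
  if (inherits(counts, "count_matrix")) {
    gene_lengths <- gene_lengths %||% counts$gene_lengths
    counts <- counts$counts
  }
  L <- gene_lengths[rownames(counts)]
  if (any(is.na(L)) || any(L <= 0)) stopf("gene lengths must be > 0 for all genes")
  r <- counts / L
  cs <- colSums(r)
  zero <- cs == 0
  cs[zero] <- 1
  out <- sweep(r, 2, cs, "/") * 1e6
  attr(out, "zero_columns") <- colnames(counts)[zero]
  out
}

# Per-gene method-of-moments NB dispersion about group means on
# normalized counts, floored at the pooled (median) estimate.
mom_dispersion <- function(N, group) {
  g <- as.factor(group)
  mu <- t(apply(N, 1, function(x) tapply(x, g, mean)[as.character(g)]))
  df <- ncol(N) - nlevels(g)
  s2 <- rowSums((N - mu)^2) / df
  mu_bar <- rowMeans(N)
  alpha <- (s2 - mu_bar) / mu_bar^2
  alpha[!is.finite(alpha)] <- NA
  floor_pooled <- stats::median(alpha[alpha > 0], na.rm = TRUE)
  if (!is.finite(floor_pooled)) floor_pooled <- 0.01
  pmax(alpha, floor_pooled, 1e-8, na.rm = TRUE)
}

#' Simplified negative-binomial differential expression
#'
#' A deliberately transparent stand-in for a full DESeq2-style analysis:
#' counts are normalized by median-of-ratios size factors (entering the
#' GLM as offsets), per-gene dispersions come from a method-of-moments
#' estimate floored at the pooled median (no shrinkage towards a fitted
#' trend, no LFC shrinkage, no outlier handling), and either a two-group
#' Wald test (`mode = "wald"`, z against the standard normal) or a
#' likelihood-ratio test (`mode = "lrt"`) of the full model
#' `~ partner + day + partner:day` against the reduced `~ day` is run,
#' with the deviance difference referred to a chi-square on the
#' difference in parameters. BH adjustment is applied across tested
#' genes; genes whose normalized base mean falls below
#' `min_base_mean` are reported with `padj = NA` (independent-filtering
#' floor), and genes with zero variance across all samples are excluded
#' from testing (`tested = FALSE`).
#'
#' @param counts a `count_matrix` or genes x samples integer matrix.
#' @param samples sample metadata (needed for `mode = "lrt"`; taken from
#'   the `count_matrix` if absent). Must have `partner` and `day`.
#' @param mode `"wald"` (two groups) or `"lrt"`.
#' @param group for Wald: factor/character of length n samples with
#'   exactly two levels, or the name of a column in `samples`.
#' @param ref for Wald: the reference level (log2FC is alt vs ref).
#' @param min_base_mean independent-filtering floor on the normalized
#'   base mean.
#' @param pseudo_reference passed to [size_factors()].
#' @return data frame of class `de_result`: gene_id, baseMean, log2FC,
#'   lfcSE, stat, pvalue, padj, dispersion, tested.
#' @export
differential_expression <- function(counts, samples = NULL,
                                    mode = c("wald", "lrt"), group = NULL,
                                    ref = NULL, min_base_mean = 1,
                                    pseudo_reference = FALSE) {
  mode <- match.arg(mode)
  if (inherits(counts, "count_matrix")) {
    samples <- samples %||% counts$samples
    counts <- counts$counts
  }
  K <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (nrow(K) == 0L) stopf("no nonzero genes to test")
  sf <- size_factors(K, pseudo_reference)
  N <- sweep(K, 2, sf, "/")
  baseMean <- rowMeans(N)
  if (mode == "wald") {
    if (is.null(group)) stopf("mode='wald' needs a two-level group")
    if (is.character(group) && length(group) == 1L)
      group <- samples[[group]]
    group <- as.factor(group)
    if (nlevels(group) != 2L) stopf("Wald mode requires exactly two groups")
    if (!is.null(ref)) group <- stats::relevel(group, ref)
    if (min(table(group)) < 2L) stopf("need >= 2 replicates per group")
    X <- stats::model.matrix(~group)
    disp_groups <- group
  } else {
    if (is.null(samples)) stopf("mode='lrt' needs sample metadata")
    partner <- as.factor(samples$partner)
    day <- as.factor(samples$day)
    if (min(table(partner, day)) < 2L)
      stopf("need >= 2 replicates per partner x day cell")
    X <- stats::model.matrix(~partner * day)
    X0 <- stats::model.matrix(~day)
    disp_groups <- interaction(partner, day)
  }
  disp <- mom_dispersion(N, disp_groups)
  off <- log(sf)
  ng <- nrow(K)
  res <- data.frame(gene_id = rownames(K), baseMean = baseMean,
                    log2FC = NA_real_, lfcSE = NA_real_, stat = NA_real_,
                    pvalue = NA_real_, padj = NA_real_, dispersion = disp,
                    tested = TRUE, stringsAsFactors = FALSE)
  zero_var <- apply(K, 1, function(x) stats::var(x) == 0)
  for (i in seq_len(ng)) {
    if (zero_var[i]) { res$tested[i] <- FALSE; next }
    fam <- MASS::negative.binomial(theta = 1 / disp[i])
    y <- K[i, ]
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = fam, offset = off)),
      error = function(e) NULL)
    if (is.null(fit)) { res$tested[i] <- FALSE; next }
    if (mode == "wald") {
      cf <- fit$coefficients[2]
      # Fisher information from the IRLS weights
      W <- fit$weights
      XtWX <- crossprod(X * W, X)
      se <- tryCatch(sqrt(diag(solve(XtWX)))[2], error = function(e) NA)
      z <- cf / se
      res$log2FC[i] <- cf / log(2)
      res$lfcSE[i] <- se / log(2)
      res$stat[i] <- z
      res$pvalue[i] <- 2 * stats::pnorm(-abs(z))
    } else {
      fit0 <- tryCatch(
        suppressWarnings(stats::glm.fit(X0, y, family = fam, offset = off)),
        error = function(e) NULL)
      if (is.null(fit0)) { res$tested[i] <- FALSE; next }
      dstat <- fit0$deviance - fit$deviance
      df <- ncol(X) - ncol(X0)
      pcoef <- fit$coefficients[grep("partner", colnames(X))]
      pcoef <- pcoef[is.finite(pcoef)]
      res$log2FC[i] <- if (length(pcoef))
        pcoef[which.max(abs(pcoef))] / log(2) else 0
      res$stat[i] <- dstat
      res$pvalue[i] <- stats::pchisq(dstat, df, lower.tail = FALSE)
    }
  }
  eligible <- res$tested & !is.na(res$pvalue) & res$baseMean >= min_base_mean
  res$padj[eligible] <- stats::p.adjust(res$pvalue[eligible], method = "BH")
  class(res) <- c("de_result", class(res))
  attr(res, "mode") <- mode
  attr(res, "size_factors") <- sf
  res
}

#' Check that multiplexing leaves gene expression unchanged
#'
#' Runs the deconvolution on two arms built from the same samples — one
#' library per sample (singleplex) versus pooled libraries (multiplex) —
#' and reports the agreement: per-gene Pearson correlation of
#' log-normalized counts, whether unique-gene counts are identical, and
#' the number of genes flagged differentially expressed between arms
#' (Wald, padj <= 0.05 and |log2FC| > 1).
#'
#' @param reads a [gen_reads()] result covering all samples involved.
#' @param multiplex_sets list of sample-id vectors defining the pooled
#'   libraries; their union must equal the singleplex sample set.
#' @param index a [build_reference_index()].
#' @param design the [synth_design()].
#' @param ... passed to [deconvolve_libraries()].
#' @return list: `r` (Pearson correlation on log2 normalized counts + 1),
#'   `identical_counts` (logical, all genes), `n_de` (genes DE between
#'   arms), `single` and `multi` count matrices.
#' @export
multiplex_fidelity <- function(reads, multiplex_sets, index, design, ...) {
  if (length(multiplex_sets) == 0L) stopf("empty multiplex list")
  sids <- unlist(multiplex_sets)
  if (anyDuplicated(sids)) stopf("a sample appears in two multiplex sets")
  if (!setequal(sids, names(reads$reads)))
    stopf("multiplex arm sample set differs from the singleplex arm")
  single_libs <- reads$reads
  single <- deconvolve_libraries(
    single_libs, index, design,
    lib_samples = as.list(stats::setNames(names(single_libs),
                                          names(single_libs))), ...)
  muxed <- multiplex_reads(reads, multiplex_sets)
  if (is.null(names(multiplex_sets)))
    names(multiplex_sets) <- names(muxed)
  multi <- deconvolve_libraries(muxed, index, design,
                                lib_samples = multiplex_sets, ...)
  K1 <- single$counts[, sids, drop = FALSE]
  K2 <- multi$counts[, sids, drop = FALSE]
  sf1 <- size_factors(K1 + K2, pseudo_reference = TRUE)  # common scale
  l1 <- log2(sweep(K1, 2, sf1, "/") + 1)
  l2 <- log2(sweep(K2, 2, sf1, "/") + 1)
  keep <- rowSums(K1 + K2) > 0
  r <- stats::cor(as.vector(l1[keep, ]), as.vector(l2[keep, ]))
  both <- cbind(K1, K2)
  colnames(both) <- c(paste0(sids, ".single"), paste0(sids, ".multi"))
  de <- differential_expression(both[rowSums(both) > 0, , drop = FALSE],
                                mode = "wald",
                                group = rep(c("single", "multi"),
                                            each = length(sids)),
                                ref = "single", pseudo_reference = TRUE)
  n_de <- sum(de$padj <= 0.05 & abs(de$log2FC) > 1, na.rm = TRUE)
  list(r = r, identical_counts = identical(unname(K1), unname(K2)),
       n_de = n_de, single = single, multi = multi, de = de)
}
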