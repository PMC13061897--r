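#' Remove noise features by replicate presence and blank ratio
#'
#' A feature is kept iff (a) it is observed (non-missing) in at least
#' `min_present_frac` of the replicates of at least one condition-by-day
#' group, and (b) its mean intensity across biological samples is at
#' least `blank_ratio` times its mean intensity across blank/agar
#' injections. Set `blank_ratio = 0` to skip the blank filter.
#'
#' @param table a [peak_table()].
#' @param min_present_frac fraction in (0, 1].
#' @param blank_ratio sample/blank mean-intensity ratio threshold.
#' @return filtered [peak_table()].
#' @export
filter_features <- function(table, min_present_frac = 2 / 3, blank_ratio = 3) {
  I <- table$intensity
  sm <- table$samples
  bio <- sm$role == "sample"
  grp <- interaction(sm$focal[bio], sm$partner[bio], sm$day[bio], drop = TRUE)
  pres <- !is.na(I[, bio, drop = FALSE])
  frac_by_grp <- vapply(levels(grp), function(l)
    rowMeans(pres[, grp == l, drop = FALSE]), numeric(nrow(I)))
  frac_by_grp <- matrix(frac_by_grp, nrow = nrow(I))
  keep_presence <- apply(frac_by_grp, 1, max) >= min_present_frac
  keep_blank <- rep(TRUE, nrow(I))
  if (blank_ratio > 0) {
    blk <- sm$role == "blank"
    if (!any(blk)) stopf("blank-ratio filtering requested but table has no blanks")
    mb <- rowMeans(I[, blk, drop = FALSE], na.rm = TRUE)
    ms <- rowMeans(I[, bio, drop = FALSE], na.rm = TRUE)
    mb[is.nan(mb)] <- 0
    keep_blank <- ms >= blank_ratio * mb
  }
  keep <- keep_presence & keep_blank
  out <- peak_table(I[keep, , drop = FALSE],
                    table$features[keep, , drop = FALSE], sm, table$log)
  pt_log(out, "filter_features", removed = sum(!keep),
         min_present_frac = min_present_frac, blank_ratio = blank_ratio)
}

# union-find for single-linkage grouping
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Collapse related peaks to one representative per molecule
#'
#' Features that co-elute (retention times within `rt_window` seconds)
#' and whose intensity profiles correlate at or above `min_corr` (Pearson,
#' pairwise-complete) are grouped by single linkage; only the most intense
#' peak of each group (highest mean intensity) is retained, standing in
#' for the "one peak per molecule" collapsing of adducts, isotopologues
#' and fragments.
#'
#' @param table a [peak_table()].
#' @param rt_window co-elution window in seconds.
#' @param min_corr minimum Pearson correlation.
#' @return [peak_table()] of representatives; the output feature table
#'   gains `group_id`, `group_size` and `group_members` columns.
#' @export
group_related_peaks <- function(table, rt_window = 5, min_corr = 0.9) {
  I <- table$intensity
  if (ncol(I) < 3L) stopf("need >= 3 samples to correlate profiles")
  nf <- nrow(I)
  rt <- table$features$rt
  ord <- order(rt)
  parent <- seq_len(nf)
  # candidate pairs: rt within window (sliding over rt-sorted features)
  for (a in seq_len(nf - 1L)) {
    i <- ord[a]
    b <- a + 1L
    while (b <= nf && rt[ord[b]] - rt[i] <= rt_window) {
      j <- ord[b]
      cc <- suppressWarnings(stats::cor(I[i, ], I[j, ],
                                        use = "pairwise.complete.obs"))
      if (!is.na(cc) && cc >= min_corr) {
        ri <- uf_find(parent, i); rj <- uf_find(parent, j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      b <- b + 1L
    }
  }
  root <- vapply(seq_len(nf), function(i) uf_find(parent, i), 0L)
  mean_int <- rowMeans(I, na.rm = TRUE)
  groups <- split(seq_len(nf), root)
  reps <- vapply(groups, function(members)
    members[which.max(mean_int[members])], 0L)
  reps <- sort(reps)
  feats <- table$features[reps, , drop = FALSE]
  grp_of <- root[reps]
  feats$group_id <- sprintf("G%04d", match(grp_of, unique(root)))
  feats$group_size <- vapply(grp_of, function(r) length(groups[[as.character(r)]]), 0L)
  feats$group_members <- vapply(grp_of, function(r)
    paste(table$features$feature_id[groups[[as.character(r)]]], collapse = ";"), "")
  out <- peak_table(I[reps, , drop = FALSE], feats, table$samples, table$log)
  pt_log(out, "group_related_peaks", n_groups = length(groups),
         rt_window = rt_window, min_corr = min_corr)
}

#' QC-anchored signal drift and batch-effect correction
#'
#' Per feature and batch, a smoother of log2 QC intensity versus
#' injection order is fitted (GCV cubic smoothing spline when at least
#' `spline_min` QC points are usable, a linear fit otherwise); every
#' injection in the batch is divided by the interpolated fit and rescaled
#' to the feature's grand QC median, which simultaneously flattens
#' within-batch drift and removes step offsets between batches. Features
#' with fewer than `min_qc` usable QC points in a batch pass through
#' unchanged there and are flagged.
#'
#' @param table a [peak_table()] with QC injections.
#' @param min_qc minimum usable QC points per batch per feature (>= 4).
#' @param spline_min QC points required before the spline is preferred
#'   over a linear fit.
#' @return corrected [peak_table()]; flagged features are recorded in the
#'   processing log entry.
#' @export
drift_correct <- function(table, min_qc = 4L, spline_min = 6L) {
  I <- table$intensity
  sm <- table$samples
  out <- I
  flagged <- character(0)
  qc_all <- sm$role == "QC"
  grand_med <- apply(I[, qc_all, drop = FALSE], 1, stats::median,
                     na.rm = TRUE)
  for (b in unique(sm$batch)) {
    in_b <- which(sm$batch == b)
    qc_b <- in_b[sm$role[in_b] == "QC"]
    if (length(qc_b) < min_qc)
      stopf("batch %s has %d QC injections; >= %d required", b,
            length(qc_b), min_qc)
    xq <- sm$injection_order[qc_b]
    xa <- sm$injection_order[in_b]
    for (f in seq_len(nrow(I))) {
      yq <- I[f, qc_b]
      use <- !is.na(yq) & yq > 0
      if (sum(use) < min_qc) {
        flagged <- c(flagged, rownames(I)[f])
        next
      }
      ly <- log2(yq[use]); lx <- xq[use]
      pred <- NULL
      if (sum(use) >= spline_min) {
        sp <- tryCatch(suppressWarnings(
          stats::smooth.spline(lx, ly, cv = FALSE)), error = function(e) NULL)
        if (!is.null(sp)) pred <- stats::predict(sp, xa)$y
      }
      if (is.null(pred)) {
        lmf <- stats::lm(ly ~ lx)
        pred <- stats::predict(lmf, data.frame(lx = xa))
      }
      fit_lin <- 2^pred
      out[f, in_b] <- I[f, in_b] / fit_lin * grand_med[f]
    }
  }
  flagged <- unique(flagged)
  res <- peak_table(out, table$features, sm, table$log)
  res <- pt_log(res, "drift_correct", flagged = flagged, min_qc = min_qc)
  attr(res, "drift_flagged") <- flagged
  res
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution: the reference spectrum is the
#' feature-wise median of the QC injections (`reference = "qc"`) or of
#' all samples (`"median"`); each sample's dilution factor is the median
#' over shared non-missing features of sample/reference quotients, and
#' the whole sample is divided by it. Before the reference is taken,
#' every column is prescaled by its own median, which makes the
#' reference invariant under per-sample dilution: the operation is then
#' exactly idempotent (re-running it returns factors of 1) and exactly
#' scale-equivariant (multiplying one sample by a constant changes
#' nothing after normalization).
#'
#' @param table a [peak_table()].
#' @param reference `"qc"` or `"median"`.
#' @return normalized [peak_table()]; factors stored in the log entry
#'   and in `attr(, "pqn_factors")`.
#' @export
pqn_normalize <- function(table, reference = c("qc", "median")) {
  reference <- match.arg(reference)
  I <- table$intensity
  cols <- if (reference == "qc") which(table$samples$role == "QC")
          else seq_len(ncol(I))
  if (!length(cols)) stopf("no QC samples available for reference = 'qc'")
  col_med <- apply(I, 2, stats::median, na.rm = TRUE)
  scaled <- sweep(I, 2, col_med, "/")    # dilution-invariant view
  ref <- apply(scaled[, cols, drop = FALSE], 1, stats::median, na.rm = TRUE)
  factors <- vapply(seq_len(ncol(I)), function(j) {
    shared <- !is.na(I[, j]) & !is.na(ref) & ref > 0
    if (!any(shared))
      stopf("sample %s shares no non-missing feature with the reference",
            colnames(I)[j])
    stats::median(I[shared, j] / ref[shared])
  }, 0)
  out <- sweep(I, 2, factors, "/")
  res <- peak_table(out, table$features, table$samples, table$log)
  res <- pt_log(res, "pqn_normalize", reference = reference,
                factors = stats::setNames(factors, colnames(I)))
  attr(res, "pqn_factors") <- stats::setNames(factors, colnames(I))
  res
}

#' Impute missing intensities by k nearest neighbours
#'
#' A missing cell `I[f, s]` is replaced by the mean of `I[f, s']` over
#' the `k` samples nearest to `s` in Euclidean distance computed on
#' co-observed features and normalized by the number of co-observed
#' features (so samples with different missingness are comparable).
#' Neighbours lacking an observation for the feature being imputed are
#' skipped; if fewer than `k` usable neighbours exist, all available are
#' used with a warning.
#'
#' @param table a [peak_table()].
#' @param k number of neighbours (>= 1).
#' @return complete [peak_table()] (no missing cells).
#' @export
knn_impute <- function(table, k = 5L) {
  if (k < 1) stopf("k must be >= 1")
  I <- table$intensity
  if (any(rowSums(!is.na(I)) == 0L))
    stopf("every feature needs >= 1 observed value")
  if (!anyNA(I)) return(pt_log(table, "knn_impute", k = k, imputed = 0L))
  ns <- ncol(I)
  obs <- !is.na(I)
  # pairwise normalized distances between samples
  D <- matrix(Inf, ns, ns)
  for (a in seq_len(ns - 1L)) for (b in (a + 1L):ns) {
    co <- obs[, a] & obs[, b]
    if (any(co)) D[a, b] <- D[b, a] <- sqrt(mean((I[co, a] - I[co, b])^2))
  }
  short <- FALSE
  n_imp <- 0L
  for (s in seq_len(ns)) {
    miss <- which(!obs[, s])
    if (!length(miss)) next
    ord <- order(D[, s])
    ord <- ord[ord != s & is.finite(D[ord, s])]
    for (f in miss) {
      nb <- ord[obs[f, ord]]
      if (!length(nb)) next
      if (length(nb) < k) short <- TRUE
      use <- nb[seq_len(min(k, length(nb)))]
      I[f, s] <- mean(I[f, use])
      n_imp <- n_imp + 1L
    }
  }
  if (anyNA(I))
    stopf("imputation left missing cells (no usable neighbours)")
  if (short) warnf("fewer than k=%d usable neighbours for some cells; used all available", k)
  res <- peak_table(I, table$features, table$samples, table$log)
  pt_log(res, "knn_impute", k = k, imputed = n_imp)
}

glog <- function(x, lambda) log2((x + sqrt(x^2 + lambda)) / 2)

#' Generalised-logarithm variance stabilization
#'
#' Applies `g(x) = log2((x + sqrt(x^2 + lambda)) / 2)`; at `lambda = 0`
#' this is exactly `log2(x)`. In `"auto"` mode lambda is chosen by a 1-D
#' bounded search (on log10 lambda) minimizing the absolute slope of the
#' SD-versus-mean trend across feature bins of the QC injections (all
#' samples if there are no QCs) — the flatter that trend, the better the
#' variance stabilization.
#'
#' @param table a [peak_table()] with complete, non-negative intensities.
#' @param lambda non-negative numeric, or `"auto"`.
#' @param bins number of feature bins for the SD-vs-mean trend.
#' @return transformed [peak_table()]; the chosen lambda is stored in the
#'   log and the pre-transform matrix in `attr(, "pre_glog")`.
#' @export
glog_transform <- function(table, lambda = "auto", bins = 10L) {
  I <- table$intensity
  if (anyNA(I)) stopf("glog requires a complete matrix; impute first")
  if (any(I < 0)) stopf("glog requires non-negative intensities")
  if (is.numeric(lambda) && lambda < 0) stopf("lambda must be >= 0")
  sd_mean_slope <- function(M) {
    fm <- rowMeans(M)
    fs <- apply(M, 1, stats::sd)
    if (length(unique(fm)) < 3) return(0)
    bin <- cut(rank(fm, ties.method = "first"), bins)
    bm <- tapply(fm, bin, stats::median)
    bs <- tapply(fs, bin, stats::median)
    ok <- is.finite(bm) & is.finite(bs)
    if (sum(ok) < 3) return(0)
    unname(stats::coef(stats::lm(bs[ok] ~ bm[ok]))[2])
  }
  if (identical(lambda, "auto")) {
    qc <- which(table$samples$role == "QC")
    M <- if (length(qc) >= 3) I[, qc, drop = FALSE] else I
    obj <- function(l10) abs(sd_mean_slope(glog(M, 10^l10)))
    opt <- stats::optimize(obj, c(-2, 2 * log10(max(M) + 1) + 2))
    lambda <- 10^opt$minimum
  }
  out <- glog(I, lambda)
  res <- peak_table(out, table$features, table$samples, table$log,
                    nonneg = FALSE)
  res <- pt_log(res, "glog_transform", lambda = lambda)
  attr(res, "pre_glog") <- I
  attr(res, "glog_lambda") <- lambda
  res
}
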