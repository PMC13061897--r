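# Row-wise Welch two-sample t-tests: X, Y are features x replicates.
row_welch_t <- function(X, Y) {
  nx <- ncol(X); ny <- ncol(Y)
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- apply(X, 1, stats::var); vy <- apply(Y, 1, stats::var)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate: both groups constant
  zero <- se2 == 0
  t[zero] <- 0; p[zero] <- 1; df[zero] <- nx + ny - 2
  data.frame(t = t, df = df, p = p)
}

#' Run the fixed metabolomics preprocessing chain
#'
#' Applies, in the stated order: feature filtering, related-peak
#' collapsing, QC-anchored drift/batch correction, probabilistic quotient
#' normalization, k-nearest-neighbour imputation, and glog variance
#' stabilization. Missing values are deliberately not imputed before
#' drift correction or PQN (both operate on observed cells only);
#' imputation sits between normalization and the variance-stabilizing
#' transform. Each step appends to the table's processing log.
#'
#' @param table a raw [peak_table()].
#' @param min_present_frac,blank_ratio see [filter_features()].
#' @param rt_window,min_corr see [group_related_peaks()].
#' @param k see [knn_impute()].
#' @param lambda see [glog_transform()].
#' @param drift apply [drift_correct()] (needs QC injections).
#' @param group_peaks apply [group_related_peaks()].
#' @return glog-scale [peak_table()] with the pre-glog normalized matrix
#'   in `attr(, "pre_glog")`.
#' @export
preprocess_peaks <- function(table, min_present_frac = 2 / 3,
                             blank_ratio = 3, rt_window = 5, min_corr = 0.9,
                             k = 5L, lambda = "auto", drift = TRUE,
                             group_peaks = TRUE) {
  out <- filter_features(table, min_present_frac, blank_ratio)
  if (group_peaks) out <- group_related_peaks(out, rt_window, min_corr)
  if (drift) out <- drift_correct(out)
  out <- pqn_normalize(out)
  out <- knn_impute(out, k)
  glog_transform(out, lambda)
}

#' Attribute metabolite features to producer strains (dual contrast)
#'
#' Implements the two-comparison selection rule for "features produced by
#' focal strain X in response to partner Y": per feature and day, Welch
#' t-tests on the glog scale compare X-Y against X-X (self pairing) and
#' X-Y against Y-X (the partner's mirror sample); log2 fold changes are
#' computed from the pre-glog normalized group means (glog compresses
#' fold changes, so the stated threshold only makes sense on the
#' intensity scale). P-values are BH-adjusted per contrast per day across
#' features (each day is an independent screen; `bh_scope = "global"`
#' pools all days of a contrast). A feature is selected iff, for each of
#' the two contrasts, some day shows `padj <= alpha` and
#' `log2FC >= lfc_min` — an increase only, matching a strong
#' statistically significant increase; `strict_same_day` requires the
#' same day to pass in both contrasts; `direction = "both"` admits
#' decreases at `log2FC <= -lfc_min`. A compound diffusing between the
#' paired colonies elevates X-Y and Y-X alike, zeroes the second
#' contrast's fold change, and is never selected — the diffusion caveat
#' built into the design.
#'
#' @param table glog-scale [peak_table()] (from [glog_transform()] or
#'   [preprocess_peaks()]); a non-transformed table is accepted and then
#'   also supplies the fold-change scale.
#' @param focal producer candidate strain X.
#' @param partner partner strain Y (must differ from X).
#' @param alpha BH-adjusted significance threshold.
#' @param lfc_min minimum log2 fold change (increase).
#' @param strict_same_day require one day passing both contrasts.
#' @param direction `"increase"` (default) or `"both"`.
#' @param bh_scope `"per_day"` or `"global"`.
#' @return object of class `attribution_result`: `stats` (long data
#'   frame: feature_id, contrast, day, log2FC, t, p, padj), `selected`
#'   (named logical per feature), `focal`, `partner`.
#' @export
attribute_producers <- function(table, focal, partner, alpha = 0.05,
                                lfc_min = 1.5, strict_same_day = FALSE,
                                direction = c("increase", "both"),
                                bh_scope = c("per_day", "global")) {
  direction <- match.arg(direction)
  bh_scope <- match.arg(bh_scope)
  if (focal == partner) stopf("focal and partner must differ")
  G <- table$intensity
  lin <- attr(table, "pre_glog") %||% table$intensity
  sm <- table$samples
  bio <- sm$role == "sample"
  lab <- function(f, p) bio & sm$focal == f & sm$partner == p
  need <- list(XY = lab(focal, partner), XX = lab(focal, focal),
               YX = lab(partner, focal))
  missing_grp <- names(need)[vapply(need, sum, 0L) == 0]
  if (length(missing_grp))
    stopf("missing condition group(s): %s (need %s-%s, %s-%s, %s-%s)",
          paste(missing_grp, collapse = ", "), focal, partner,
          focal, focal, partner, focal)
  days <- sort(Reduce(intersect, lapply(need, function(ix)
    unique(sm$day[which(ix)]))))
  if (!length(days)) stopf("no day sampled in all three condition groups")
  rows <- list()
  for (d in days) {
    xy <- which(need$XY & sm$day == d)
    for (ct in c("XY_vs_XX", "XY_vs_YX")) {
      other <- if (ct == "XY_vs_XX") which(need$XX & sm$day == d)
               else which(need$YX & sm$day == d)
      if (length(xy) < 2 || length(other) < 2)
        stopf("need >= 2 replicates per condition per day (day %s)", d)
      tt <- row_welch_t(G[, xy, drop = FALSE], G[, other, drop = FALSE])
      lfc <- log2(rowMeans(lin[, xy, drop = FALSE]) /
                    rowMeans(lin[, other, drop = FALSE]))
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = rownames(G), contrast = ct, day = d,
        log2FC = lfc, t = tt$t, p = tt$p, padj = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  st <- do.call(rbind, rows)
  rownames(st) <- NULL
  if (bh_scope == "per_day") {
    for (ct in unique(st$contrast)) for (d in days) {
      ix <- st$contrast == ct & st$day == d
      st$padj[ix] <- stats::p.adjust(st$p[ix], method = "BH")
    }
  } else {
    for (ct in unique(st$contrast)) {
      ix <- st$contrast == ct
      st$padj[ix] <- stats::p.adjust(st$p[ix], method = "BH")
    }
  }
  pass <- st$padj <= alpha &
    (st$log2FC >= lfc_min |
       (direction == "both" & st$log2FC <= -lfc_min))
  fid <- rownames(G)
  hit <- function(ct) {
    m <- matrix(FALSE, length(fid), length(days),
                dimnames = list(fid, as.character(days)))
    ix <- which(st$contrast == ct & pass)
    m[cbind(match(st$feature_id[ix], fid),
            match(as.character(st$day[ix]), as.character(days)))] <- TRUE
    m
  }
  h1 <- hit("XY_vs_XX"); h2 <- hit("XY_vs_YX")
  selected <- if (strict_same_day) apply(h1 & h2, 1, any)
              else apply(h1, 1, any) & apply(h2, 1, any)
  structure(list(stats = st, selected = selected, focal = focal,
                 partner = partner, alpha = alpha, lfc_min = lfc_min,
                 days = days),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("attribution_result: produced by %s in response to %s; %d/%d features selected\n",
              x$focal, x$partner, sum(x$selected), length(x$selected)))
  invisible(x)
}

#' Row-scale a matrix to Z-scores
#'
#' Each row is centred to mean 0 and scaled to SD 1 (sample SD, n - 1
#' denominator). Constant rows cannot be scaled: they come back all-zero
#' and are flagged in `attr(, "constant_rows")`.
#'
#' @param m numeric matrix.
#' @return Z-scored matrix.
#' @export
row_zscore <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  const <- sd == 0 | is.na(sd)
  sd[const] <- 1
  out <- (m - mu) / sd
  out[const, ] <- 0
  attr(out, "constant_rows") <- rownames(m)[const]
  out
}
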