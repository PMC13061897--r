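#' Construct a feature-by-sample LC-MS peak table
#'
#' The central metabolomics container: an intensity matrix (arbitrary
#' units, NA = missing) with feature metadata (m/z, retention time in
#' seconds, polarity) and sample metadata (focal, partner, day, replicate,
#' injection order, batch, role). Roles are `"sample"`, `"QC"` (pooled
#' quality control injections) and `"blank"` (agar/solvent controls).
#'
#' @param intensity numeric matrix, features x samples; dimnames required.
#' @param features data frame with at least feature_id, mz, rt, polarity;
#'   rows match `rownames(intensity)`.
#' @param samples data frame with at least sample_id, focal, partner, day,
#'   replicate, injection_order, batch, role; rows match
#'   `colnames(intensity)`.
#' @param log list of processing-step records (appended to by each
#'   preprocessing operation).
#' @param nonneg enforce non-negative intensities (disabled for tables on
#'   a transformed scale, e.g. after glog).
#' @return object of class `peak_table`.
#' @export
peak_table <- function(intensity, features, samples, log = list(),
                       nonneg = TRUE) {
  stopifnot(is.matrix(intensity), !is.null(rownames(intensity)),
            !is.null(colnames(intensity)))
  if (!identical(rownames(intensity), features$feature_id))
    stopf("feature metadata rows must match intensity rownames")
  if (!identical(colnames(intensity), samples$sample_id))
    stopf("sample metadata rows must match intensity colnames")
  if (nonneg && any(intensity < 0, na.rm = TRUE))
    stopf("intensities must be >= 0 or missing")
  for (b in unique(samples$batch)) {
    io <- samples$injection_order[samples$batch == b]
    if (anyDuplicated(io)) stopf("injection_order not unique within batch %s", b)
  }
  bio <- samples$role == "sample"
  if (any(bio & (is.na(samples$focal) | is.na(samples$partner))))
    stopf("every biological sample needs a focal-partner label")
  structure(list(intensity = intensity, features = features,
                 samples = samples, log = log),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  tab <- table(x$samples$role)
  cat(sprintf("peak_table: %d features x %d samples (%s)\n",
              nrow(x$intensity), ncol(x$intensity),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  missing: %.1f%%; steps applied: %s\n",
              100 * mean(is.na(x$intensity)),
              if (length(x$log)) paste(vapply(x$log, `[[`, "", "step"),
                                       collapse = " -> ") else "none"))
  invisible(x)
}

pt_log <- function(table, step, ...) {
  table$log <- c(table$log, list(list(step = step, ...)))
  table
}

# Biological-sample columns (role == "sample")
pt_bio <- function(table) which(table$samples$role == "sample")

#' Write a peak table as a wide TSV plus a sample-metadata sidecar
#'
#' @param table a [peak_table()].
#' @param path path of the intensity TSV; the sidecar gets the suffix
#'   `_samples.tsv` and the feature metadata `_features.tsv`.
#' @return invisibly, the three paths.
#' @export
write_peak_table <- function(table, path) {
  wide <- data.frame(feature_id = rownames(table$intensity),
                     table$features[setdiff(names(table$features), "feature_id")],
                     table$intensity, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_tsv(wide, path)
  base <- sub("\\.tsv$", "", path)
  sp <- paste0(base, "_samples.tsv")
  write_tsv(table$samples, sp)
  invisible(c(path, sp))
}

#' Read a peak table written by [write_peak_table()]
#' @param path intensity TSV path (sidecar inferred).
#' @return a [peak_table()].
#' @export
read_peak_table <- function(path) {
  wide <- read_tsv(path)
  samples <- read_tsv(paste0(sub("\\.tsv$", "", path), "_samples.tsv"))
  meta_cols <- intersect(c("feature_id", "mz", "rt", "polarity"), names(wide))
  ints <- as.matrix(wide[, samples$sample_id, drop = FALSE])
  rownames(ints) <- wide$feature_id
  peak_table(ints, wide[, meta_cols, drop = FALSE], samples)
}
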