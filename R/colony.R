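#' Otsu's threshold for a grayscale image
#'
#' Classic histogram-based threshold maximizing between-class variance,
#' on 256 bins over [0, 1]. Parameter-free, which keeps segmentation of
#' the synthetic fixtures reproducible.
#'
#' @param img numeric matrix in [0, 1].
#' @return scalar threshold in (0, 1).
#' @export
otsu_threshold <- function(img) {
  h <- tabulate(pmin(pmax(floor(img * 256) + 1L, 1L), 256L), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 0.5) / 256)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) / 256
}

# 8-connected component labelling via row-run union-find.
# Returns a data frame of components: area_px, cx, cy, bbox, fill ratio.
label_components <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  runs <- list()   # per row: data.frame(start, end, id)
  parent <- integer(0)
  nid <- 0L
  prev <- NULL
  for (r in seq_len(nr)) {
    v <- bin[r, ]
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    fg <- which(rl$values)
    cur <- if (length(fg))
      data.frame(start = starts[fg], end = ends[fg],
                 id = nid + seq_along(fg)) else NULL
    if (!is.null(cur)) {
      nid <- nid + nrow(cur)
      parent <- c(parent, cur$id)
      if (!is.null(prev)) {
        for (i in seq_len(nrow(cur))) {
          # 8-connectivity: overlap with one-pixel diagonal tolerance
          touch <- prev$start <= cur$end[i] + 1L & prev$end >= cur$start[i] - 1L
          for (j in which(touch)) {
            a <- uf_find(parent, cur$id[i]); b <- uf_find(parent, prev$id[j])
            if (a != b) parent[max(a, b)] <- min(a, b)
          }
        }
      }
    }
    runs[r] <- list(cur)
    prev <- cur
  }
  if (nid == 0L)
    return(data.frame(label = integer(), area_px = numeric(), cx = numeric(),
                      cy = numeric(), xmin = integer(), xmax = integer(),
                      ymin = integer(), ymax = integer(), fill = numeric()))
  all_runs <- do.call(rbind, lapply(seq_len(nr), function(r) {
    if (is.null(runs[[r]])) return(NULL)
    cbind(runs[[r]], row = r)
  }))
  all_runs$root <- vapply(all_runs$id, function(i) uf_find(parent, i), 0L)
  agg <- lapply(split(all_runs, all_runs$root), function(g) {
    len <- g$end - g$start + 1L
    area <- sum(len)
    data.frame(area_px = area,
               cx = sum((g$start + g$end) / 2 * len) / area,
               cy = sum(g$row * len) / area,
               xmin = min(g$start), xmax = max(g$end),
               ymin = min(g$row), ymax = max(g$row))
  })
  out <- do.call(rbind, agg)
  out$label <- seq_len(nrow(out))
  out$fill <- out$area_px /
    ((out$xmax - out$xmin + 1) * (out$ymax - out$ymin + 1))
  rownames(out) <- NULL
  out[, c("label", "area_px", "cx", "cy", "xmin", "xmax", "ymin", "ymax",
          "fill")]
}

#' Segment colonies in a plate image
#'
#' Converts to grayscale, binarizes (Otsu by default, or a fixed
#' threshold), labels 8-connected foreground components, and returns
#' their pixel areas, centroids and bounding boxes sorted by area
#' descending. Thin ring-shaped components (bounding-box fill ratio below
#' `ring_fill_max` — a filled disk has ratio pi/4) are treated as the
#' plate rim, excluded from the colony list, and returned in
#' `attr(, "rings")`. Colonies grown into contact can be separated by a
#' user-supplied vertical split at the inter-inoculum midline
#' (`roi_split_x`), which blanks that pixel column before labelling.
#'
#' @param image numeric matrix (grayscale) or H x W x C array.
#' @param threshold `"otsu"` or a fixed numeric threshold in (0, 1).
#' @param min_area_px discard components smaller than this.
#' @param foreground `"bright"` (colonies brighter than agar, default) or
#'   `"dark"`.
#' @param roi_split_x optional x coordinate(s) of vertical split lines.
#' @param ring_fill_max fill-ratio cutoff below which a large component
#'   is classed as the rim.
#' @return data frame of contours (label, area_px, cx, cy, bounding box,
#'   fill), sorted by area descending; attributes `threshold` and
#'   `rings`.
#' @export
segment_colonies <- function(image, threshold = "otsu", min_area_px = 20,
                             foreground = c("bright", "dark"),
                             roi_split_x = NULL, ring_fill_max = 0.3) {
  foreground <- match.arg(foreground)
  g <- as_gray(image)
  if (length(g) == 0L || diff(range(g)) < 1e-6) {
    out <- label_components(matrix(FALSE, 1, 1))
    attr(out, "threshold") <- NA_real_
    attr(out, "rings") <- out
    return(out)
  }
  thr <- if (identical(threshold, "otsu")) otsu_threshold(g)
         else as.numeric(threshold)
  bin <- if (foreground == "bright") g > thr else g < thr
  if (!is.null(roi_split_x)) bin[, round(roi_split_x)] <- FALSE
  comp <- label_components(bin)
  comp <- comp[comp$area_px >= min_area_px, , drop = FALSE]
  rings <- comp[comp$fill < ring_fill_max, , drop = FALSE]
  comp <- comp[comp$fill >= ring_fill_max, , drop = FALSE]
  comp <- comp[order(-comp$area_px), , drop = FALSE]
  rownames(comp) <- NULL
  attr(comp, "threshold") <- thr
  attr(comp, "rings") <- rings
  comp
}

#' Estimate the plate rim diameter in pixels
#'
#' Finds the largest ring-like thresholded component (the rim circle) and
#' returns the mean of its bounding-box width and height.
#'
#' @inheritParams segment_colonies
#' @return diameter in px, or NA if no ring-like component is found.
#' @export
detect_plate_rim <- function(image, threshold = "otsu",
                             ring_fill_max = 0.3) {
  comp <- segment_colonies(image, threshold = threshold, min_area_px = 20,
                           ring_fill_max = ring_fill_max)
  rings <- attr(comp, "rings")
  if (nrow(rings) == 0L) return(NA_real_)
  r <- rings[which.max(rings$area_px), ]
  mean(c(r$xmax - r$xmin + 1, r$ymax - r$ymin + 1))
}

#' Pixel-to-millimetre conversion factor
#'
#' `c = plate_diameter_mm / plate_diameter_px` (mm per px); areas convert
#' with `c^2`.
#'
#' @param plate_diameter_px rim diameter in the image (px).
#' @param plate_diameter_mm known physical plate diameter (mm).
#' @return conversion factor c in mm/px.
#' @export
px_to_mm_factor <- function(plate_diameter_px, plate_diameter_mm) {
  if (plate_diameter_px <= 0 || plate_diameter_mm <= 0)
    stopf("plate diameters must be > 0")
  plate_diameter_mm / plate_diameter_px
}

#' Compare colony areas between partner conditions
#'
#' All pairwise two-sample Welch t-tests among conditions, BH-adjusted
#' across the pair family (`method = "ttest_bh"`), or Tukey's Honest
#' Significant Difference on the one-way layout (`method = "tukey"`).
#' Conditions with fewer than 2 replicates are excluded with a warning.
#' Pairs are reported in canonical (sorted) order; the statistics are
#' symmetric in pair order.
#'
#' @param areas numeric vector of areas (any consistent unit).
#' @param condition factor/character parallel to `areas`.
#' @param method `"ttest_bh"` or `"tukey"`.
#' @return data frame of class `area_comparison`: group1, group2,
#'   statistic, p, padj.
#' @export
compare_areas <- function(areas, condition, method = c("ttest_bh", "tukey")) {
  method <- match.arg(method)
  condition <- as.character(condition)
  tab <- table(condition)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warnf("excluding condition(s) with < 2 replicates: %s",
          paste(small, collapse = ", "))
    keep <- !condition %in% small
    areas <- areas[keep]; condition <- condition[keep]
  }
  lev <- sort(unique(condition))
  if (length(lev) < 2) stopf("need >= 2 conditions with >= 2 replicates")
  if (method == "ttest_bh") {
    prs <- utils::combn(lev, 2)
    res <- apply(prs, 2, function(pr) {
      x <- areas[condition == pr[1]]; y <- areas[condition == pr[2]]
      if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y))
        c(statistic = 0, p = 1)
      else {
        tt <- stats::t.test(x, y)
        c(statistic = unname(tt$statistic), p = tt$p.value)
      }
    })
    out <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                      statistic = res["statistic", ], p = res["p", ],
                      stringsAsFactors = FALSE)
    out$padj <- stats::p.adjust(out$p, method = "BH")
  } else {
    fit <- stats::aov(areas ~ factor(condition))
    tk <- stats::TukeyHSD(fit)[[1]]
    # rownames are "levB-levA"; level labels may themselves contain
    # hyphens, so rebuild the pair list from the level order instead
    prs <- utils::combn(lev, 2)
    rn <- paste(prs[2, ], prs[1, ], sep = "-")
    tk <- tk[match(rn, rownames(tk)), , drop = FALSE]
    out <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                      statistic = tk[, "diff"], p = tk[, "p adj"],
                      padj = tk[, "p adj"], stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  class(out) <- c("area_comparison", class(out))
  out
}

#' Summarise plate-reader well-scan grids and build a dose table
#'
#' Each well is a grid of OD readings (30 x 30 = 900 at maximum
#' resolution); a per-well scalar is taken (`mean`, `median` or
#' `integrated` = sum), and when concentrations are supplied wells are
#' joined to them into a dose-response table of replicate mean and SD,
#' with a linear fit of response versus concentration.
#'
#' @param grids named list of numeric matrices, one per well.
#' @param stat `"mean"`, `"median"` or `"integrated"`.
#' @param conc named numeric vector well -> concentration (optional).
#' @param dims declared grid dimensions; a grid of any other shape is an
#'   error.
#' @return list: `wells` (data frame well, value), and when `conc` is
#'   given `dose` (concentration, mean, sd, n) and `fit` (slope,
#'   intercept, r_squared).
#' @export
wellscan_summary <- function(grids, stat = c("mean", "median", "integrated"),
                             conc = NULL, dims = c(30L, 30L)) {
  stat <- match.arg(stat)
  bad <- vapply(grids, function(g) !all(dim(g) == dims), TRUE)
  if (any(bad)) stopf("well(s) with wrong grid shape: %s",
                      paste(names(grids)[bad], collapse = ", "))
  f <- switch(stat, mean = mean, median = stats::median, integrated = sum)
  wells <- data.frame(well = names(grids),
                      value = vapply(grids, f, 0),
                      stringsAsFactors = FALSE)
  rownames(wells) <- NULL
  out <- list(wells = wells)
  if (!is.null(conc)) {
    wells$concentration <- conc[wells$well]
    agg <- lapply(split(wells, wells$concentration), function(g)
      data.frame(concentration = g$concentration[1], mean = mean(g$value),
                 sd = stats::sd(g$value), n = nrow(g)))
    dose <- do.call(rbind, agg)
    dose <- dose[order(dose$concentration), ]
    rownames(dose) <- NULL
    fit <- stats::lm(value ~ concentration, data = wells)
    out$dose <- dose
    out$fit <- list(slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]),
                    r_squared = summary(fit)$r.squared)
    out$wells <- wells
  }
  out
}
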