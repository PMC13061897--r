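#' Render a synthetic Petri-dish image with known colony geometry
#'
#' Colonies are filled disks brighter than the agar background; the plate
#' rim is drawn as a thin circle of known pixel diameter, anchoring the
#' pixel-to-millimetre conversion downstream. Additive Gaussian noise of
#' stated SD is applied and the image clipped to [0, 1]. Overlapping
#' colonies are allowed but flagged in the returned truth table.
#'
#' @param width,height image size in pixels.
#' @param colonies data frame with columns cx, cy, radius (px) and
#'   optionally intensity (default 0.9); may have zero rows.
#' @param plate_diameter_px rim circle diameter (px), centred in the image.
#' @param background agar grey level.
#' @param rim_intensity grey level of the rim ring.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed (noise only).
#' @return list with `image` (height x width numeric matrix in [0, 1])
#'   and `truth` (data frame: cx, cy, radius, area_px = pi r^2,
#'   overlapping flag; sorted by area descending).
#' @export
gen_plate_image <- function(width = 400L, height = 400L,
                            colonies = data.frame(cx = numeric(),
                                                  cy = numeric(),
                                                  radius = numeric()),
                            plate_diameter_px = 0.9 * min(width, height),
                            background = 0.25, rim_intensity = 0.6,
                            noise_sd = 0.01, seed = 1L) {
  if (nrow(colonies) && any(colonies$radius < 1))
    stopf("colony radius must be >= 1 px")
  ctr <- c(width, height) / 2
  if (nrow(colonies)) {
    d <- sqrt((colonies$cx - ctr[1])^2 + (colonies$cy - ctr[2])^2)
    if (any(d + colonies$radius > plate_diameter_px / 2))
      stopf("colonies must lie inside the plate boundary")
  }
  if (is.null(colonies$intensity)) colonies$intensity <- rep(0.9, nrow(colonies))
  xs <- matrix(rep(seq_len(width), each = height), nrow = height)
  ys <- matrix(rep(seq_len(height), width), nrow = height)
  img <- matrix(background, nrow = height, ncol = width)
  # rim: one-and-a-half-pixel-wide ring
  rr <- sqrt((xs - ctr[1])^2 + (ys - ctr[2])^2)
  img[abs(rr - plate_diameter_px / 2) <= 1.5] <- rim_intensity
  for (i in seq_len(nrow(colonies))) {
    inside <- (xs - colonies$cx[i])^2 + (ys - colonies$cy[i])^2 <=
      colonies$radius[i]^2
    img[inside] <- colonies$intensity[i]
  }
  img <- with_seed(seed, img + matrix(stats::rnorm(length(img), 0, noise_sd),
                                      nrow = height))
  img <- pmin(pmax(img, 0), 1)
  overlapping <- rep(FALSE, nrow(colonies))
  if (nrow(colonies) > 1) {
    for (i in seq_len(nrow(colonies) - 1)) for (j in (i + 1):nrow(colonies)) {
      dd <- sqrt((colonies$cx[i] - colonies$cx[j])^2 +
                 (colonies$cy[i] - colonies$cy[j])^2)
      if (dd < colonies$radius[i] + colonies$radius[j])
        overlapping[c(i, j)] <- TRUE
    }
  }
  truth <- data.frame(cx = colonies$cx, cy = colonies$cy,
                      radius = colonies$radius,
                      area_px = pi * colonies$radius^2,
                      overlapping = overlapping)
  truth <- truth[order(-truth$area_px), , drop = FALSE]
  rownames(truth) <- NULL
  list(image = img, truth = truth,
       plate_diameter_px = plate_diameter_px)
}

#' Read a grayscale image (PNG or plain-text PGM)
#'
#' PNG is read via the png package; colour images are converted to
#' grayscale with the Rec. 601 luma weights (0.299, 0.587, 0.114), the
#' same convention OpenCV's BGR2GRAY uses. PGM must be the plain (P2)
#' format.
#'
#' @param path image path ending in .png or .pgm.
#' @return numeric matrix in [0, 1].
#' @export
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    return(as_gray(a))
  }
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
    if (txt[1] != "P2") stopf("only plain (P2) PGM is supported")
    w <- as.integer(txt[2]); h <- as.integer(txt[3])
    maxv <- as.numeric(txt[4])
    vals <- as.numeric(txt[-(1:4)]) / maxv
    return(matrix(vals, nrow = h, ncol = w, byrow = TRUE))
  }
  stopf("unsupported image format: %s", path)
}

#' Write a grayscale image (PNG or plain-text PGM)
#' @param img numeric matrix in [0, 1].
#' @param path output path ending in .png or .pgm.
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img, path)
  } else if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    v <- round(t(img) * 255)
    lines <- c("P2", paste(ncol(img), nrow(img)), "255",
               vapply(seq_len(nrow(img)), function(i)
                 paste(round(img[i, ] * 255), collapse = " "), ""))
    writeLines(lines, path)
  } else stopf("unsupported image format: %s", path)
  invisible(path)
}

#' Convert an image array to a grayscale matrix
#'
#' Matrices pass through; H x W x {2,3,4} arrays are collapsed with the
#' Rec. 601 luma weights (alpha ignored).
#'
#' @param img matrix or array as returned by [png::readPNG()].
#' @return numeric matrix.
#' @export
as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3)
      return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    return(img[, , 1])
  }
  stopf("cannot interpret image with dim %s", paste(dim(img), collapse = "x"))
}
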