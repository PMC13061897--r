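#' Simulate an LC-MS peak table with planted producer features
#'
#' Emulates the peak table an untargeted LC-MS run of the co-culture
#' design would produce after peak picking. Baseline intensities are
#' log-normal (per-feature log2 mean drawn uniformly, cell noise of
#' stated SD on the log2 scale). Planted producer features are elevated
#' by their log2 effect in the samples where the producer grows (all of
#' the producer's focal samples for constitutive features, only the
#' focal-partner pairing named by `responder` for induced ones); when the
#' `diffusible` flag is set the compound also appears, at the same
#' planted effect, in the mirrored partner samples — emulating a
#' siderophore like DFO-B diffusing from a strong producer into its
#' neighbour's agar plug. The injection sequence is randomised, pooled-QC
#' injections are placed at every `qc_every`-th position, blanks sit at
#' the start and end of each batch, a multiplicative linear intensity
#' drift of stated slope runs across the injection order, and
#' missingness is imposed preferentially at low intensities (probit on
#' log-intensity with a floor, calibrated so the overall missing fraction
#' equals `missing_rate`).
#'
#' @param design a [synth_design()].
#' @param truth a [planted_truth()]; `producer_features` may carry an
#'   optional `mz` column to pin specific features to known masses.
#' @param n_features total features (must cover the planted ones; the
#'   first `n_noise_features` of the remainder are blank-level noise).
#' @param n_noise_features features whose sample mean equals the blank
#'   mean (removed by blank-ratio filtering).
#' @param noise_sd cell noise SD on the log2 scale.
#' @param drift_slope linear drift: the multiplicative factor rises from 1
#'   to `1 + drift_slope` across the injection sequence.
#' @param n_batches consecutive batches; `batch_shift` multiplies batch b
#'   by `2^(batch_shift * (b - 1))`.
#' @param batch_shift log2 step offset between batches.
#' @param missing_rate overall fraction of missing cells in [0, 1).
#' @param qc_every QC at every `qc_every`-th injection (>= 2).
#' @param n_blanks blank injections per batch (half at start, half at end).
#' @param blank_offset log2 distance between real-feature sample level and
#'   blank level.
#' @param adduct_pairs number of real features that get a co-eluting
#'   correlated companion ion (half intensity, +21.982 m/z), exercising
#'   related-peak collapsing.
#' @param polarity ionisation mode recorded for all features.
#' @param seed RNG seed; defaults to the design seed.
#' @return a [peak_table()]; the generator parameters are kept in the
#'   first log entry and the expected (noise-free, log2) biological matrix
#'   in `attr(, "expected_log2")`.
#' @export
gen_peaktable <- function(design, truth = planted_truth(), n_features = 500L,
                          n_noise_features = 0L, noise_sd = 0.2,
                          drift_slope = 0, n_batches = 1L, batch_shift = 0,
                          missing_rate = 0, qc_every = 6L, n_blanks = 4L,
                          blank_offset = 6, adduct_pairs = 0L,
                          polarity = "+", seed = design$seed) {
  pf <- truth$producer_features
  if (n_features < nrow(pf))
    stopf("n_features must cover the %d planted features", nrow(pf))
  if (missing_rate < 0 || missing_rate >= 1)
    stopf("missing_rate must be in [0, 1)")
  if (qc_every < 2) stopf("qc_every must be >= 2")
  with_seed(seed, {
    fid <- sprintf("F%04d", seq_len(n_features))
    planted <- pf$feature_id
    if (length(planted) && !all(planted %in% fid))
      stopf("planted feature ids must be among %s..%s", fid[1], fid[n_features])
    bio <- design$samples
    nb <- nrow(bio)
    mu <- stats::runif(n_features, 10, 20)          # baseline log2 level
    names(mu) <- fid
    # expected biological log2 matrix: baseline + planted effects
    E <- matrix(rep(mu, nb), nrow = n_features,
                dimnames = list(fid, bio$sample_id))
    if (nrow(pf)) for (i in seq_len(nrow(pf))) {
      f <- pf$feature_id[i]
      produced <- bio$focal == pf$producer[i] &
        (is.na(pf$responder[i]) | bio$partner == pf$responder[i])
      E[f, produced] <- E[f, produced] + pf$lfc[i]
      if (isTRUE(pf$diffusible[i])) {
        mirror <- bio$partner == pf$producer[i] &
          (is.na(pf$responder[i]) | bio$focal == pf$responder[i]) & !produced
        E[f, mirror] <- E[f, mirror] + pf$lfc[i]
      }
    }
    noise_feature <- seq_len(n_features) > n_features - n_noise_features
    if (length(planted) && any(planted %in% fid[noise_feature]))
      stopf("planted features collide with the noise-feature block")
    # noise features carry no biology: sample level == blank level
    blank_mu <- ifelse(noise_feature, mu, mu - blank_offset)
    E[noise_feature, ] <- mu[noise_feature]

    # injection sequence per batch: blanks | randomised samples with QCs
    ord <- sample(nb)
    batch_of <- sort(rep(seq_len(n_batches), length.out = nb))
    cols <- list(); meta <- list(); inj <- 0L; qc_i <- 0L; blk_i <- 0L
    qc_log2 <- rowMeans(E)                          # pooled mean spectrum
    chunks <- split(bio$sample_id[ord], batch_of)
    add_col <- function(id, log2v, focal, partner, day, repl, role, b) {
      inj <<- inj + 1L
      cols[[length(cols) + 1L]] <<- log2v
      meta[[length(meta) + 1L]] <<- data.frame(
        sample_id = id, focal = focal, partner = partner, day = day,
        replicate = repl, injection_order = inj, batch = b, role = role,
        stringsAsFactors = FALSE)
    }
    half <- ceiling(n_blanks / 2)
    for (b in seq_along(chunks)) {
      blank_here <- function() {
        blk_i <<- blk_i + 1L
        add_col(sprintf("BLK%02d", blk_i), blank_mu, NA, NA, NA, NA, "blank", b)
      }
      for (j in seq_len(half)) blank_here()
      since_qc <- 0L
      for (sid in chunks[[b]]) {
        since_qc <- since_qc + 1L
        if (since_qc %% qc_every == 0L) {
          qc_i <- qc_i + 1L
          add_col(sprintf("QC%02d", qc_i), qc_log2, NA, NA, NA, NA, "QC", b)
        }
        sm <- bio[bio$sample_id == sid, ]
        add_col(sid, E[, sid], sm$focal, sm$partner, sm$day, sm$replicate,
                "sample", b)
      }
      for (j in seq_len(n_blanks - half)) blank_here()
    }
    samples <- do.call(rbind, meta)
    L <- do.call(cbind, cols)
    dimnames(L) <- list(fid, samples$sample_id)
    L <- L + matrix(stats::rnorm(length(L), 0, noise_sd), nrow = n_features)
    ints <- 2^L
    n_inj <- ncol(ints)
    if (drift_slope != 0)
      ints <- sweep(ints, 2, 1 + drift_slope *
                      (samples$injection_order - 1) / (n_inj - 1), "*")
    if (batch_shift != 0)
      ints <- sweep(ints, 2, 2^(batch_shift * (samples$batch - 1)), "*")

    features <- data.frame(feature_id = fid,
                           mz = round(stats::runif(n_features, 90, 1350), 4),
                           rt = round(stats::runif(n_features, 60, 600), 1),
                           polarity = polarity, stringsAsFactors = FALSE)
    if (length(planted) && "mz" %in% names(pf)) {
      ok <- !is.na(pf$mz)
      features$mz[match(pf$feature_id[ok], fid)] <- pf$mz[ok]
    }
    # co-eluting companion ions for related-peak grouping
    if (adduct_pairs > 0) {
      src <- setdiff(fid[!noise_feature], planted)[seq_len(adduct_pairs)]
      comp <- ints[src, , drop = FALSE] * 0.5 *
        2^matrix(stats::rnorm(adduct_pairs * n_inj, 0, 0.05), adduct_pairs)
      comp_id <- paste0(src, "a")
      rownames(comp) <- comp_id
      ints <- rbind(ints, comp)
      features <- rbind(features, data.frame(
        feature_id = comp_id, mz = features$mz[match(src, fid)] + 21.982,
        rt = features$rt[match(src, fid)] + stats::runif(adduct_pairs, -1, 1),
        polarity = polarity, stringsAsFactors = FALSE))
      fid <- c(fid, comp_id)
    }
    if (missing_rate > 0) {
      x <- log2(ints)
      s <- stats::sd(x)
      eps <- 0.1 * missing_rate
      pfun <- function(t) eps + (1 - eps) * stats::pnorm((t - x) / s)
      t0 <- stats::uniroot(function(t) mean(pfun(t)) - missing_rate,
                           range(x) + c(-10, 10))$root
      ints[stats::runif(length(ints)) < pfun(t0)] <- NA
    }
    out <- peak_table(ints, features, samples)
    out <- pt_log(out, "gen_peaktable", n_features = n_features,
                  n_noise_features = n_noise_features, noise_sd = noise_sd,
                  drift_slope = drift_slope, n_batches = n_batches,
                  batch_shift = batch_shift, missing_rate = missing_rate,
                  qc_every = qc_every, seed = seed)
    attr(out, "expected_log2") <- E
    attr(out, "noise_features") <- fid[seq_len(n_features)][noise_feature]
    out
  })
}
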