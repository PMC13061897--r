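# Shared fixture: a small generated table with planted producer,
# diffusible and noise features.
local({
  d <- synth_design(strains = c("A", "C"), days = 2:4, replicates = 3,
                    seed = 31)
  tr <- planted_truth(producer_features = data.frame(
    feature_id = c("F0001", "F0002"), producer = c("A", "C"),
    responder = c("C", NA), lfc = c(3, 4), diffusible = c(FALSE, TRUE),
    mz = c(NA, 281.184)))
  pt <- gen_peaktable(d, tr, n_features = 100, n_noise_features = 30,
                      noise_sd = 0.2, drift_slope = 0, missing_rate = 0)
  assign(".mfx", list(d = d, tr = tr, pt = pt), envir = topenv())
})

test_that("blank-ratio filtering removes exactly the planted noise features", {
  f <- filter_features(.mfx$pt, min_present_frac = 2 / 3, blank_ratio = 3)
  removed <- setdiff(rownames(.mfx$pt$intensity), rownames(f$intensity))
  expect_setequal(removed, attr(.mfx$pt, "noise_features"))
  # feature present only in blanks is removed; present in all kept
  I <- .mfx$pt$intensity[1:2, ]
  I[2, .mfx$pt$samples$role != "blank"] <- NA
  tab <- peak_table(I, .mfx$pt$features[1:2, ], .mfx$pt$samples)
  f2 <- filter_features(tab, min_present_frac = 0.5, blank_ratio = 0)
  expect_identical(rownames(f2$intensity), "F0001")
  expect_error(filter_features(fix_peak_table(
    matrix(1, 1, 4, dimnames = list("F1", sprintf("A-A_d2_r%d", 1:4))))),
    "no blanks")
})

test_that("related-peak collapsing keeps the most intense co-eluting profile", {
  set.seed(5)
  base <- 2^rnorm(9, 14, 1)
  I <- rbind(F1 = base * 2, F2 = base, F3 = 2^rnorm(9, 14, 1))
  colnames(I) <- sprintf("A-%s_d%d_r%d", rep(c("A", "C", "A"), 3),
                         rep(2:4, each = 3), rep(1:3, 3))
  colnames(I) <- sprintf("A-A_d2_r%d", 1:9)
  tab <- fix_peak_table(I, rt = c(100, 101, 400))
  g <- group_related_peaks(tab, rt_window = 5, min_corr = 0.9)
  expect_true("F1" %in% rownames(g$intensity))     # 2:1 -> intense kept
  expect_false("F2" %in% rownames(g$intensity))
  expect_true("F3" %in% rownames(g$intensity))     # far in RT: never grouped
  expect_equal(g$features$group_size[g$features$feature_id == "F1"], 2)
  # generator truth: planted adduct companions collapse onto their parents
  d <- .mfx$d
  pt2 <- gen_peaktable(d, n_features = 40, adduct_pairs = 6, seed = 8)
  g2 <- group_related_peaks(pt2, rt_window = 5, min_corr = 0.9)
  expect_equal(nrow(g2$intensity), 40)             # one per molecule
  expect_false(any(grepl("a$", rownames(g2$intensity))))
})

test_that("drift correction is a no-op on flat QCs and flattens planted drift", {
  d <- .mfx$d
  p0 <- gen_peaktable(d, n_features = 30, noise_sd = 0, drift_slope = 0)
  dc <- drift_correct(p0)
  expect_equal(dc$intensity, p0$intensity, tolerance = 1e-8)
  # planted x2 drift across the run: QC RSD must drop
  p1 <- gen_peaktable(d, n_features = 30, noise_sd = 0.1, drift_slope = 1)
  dc1 <- drift_correct(p1)
  qc <- p1$samples$role == "QC"
  rsd <- function(M) stats::median(apply(M[, qc], 1, function(x)
    stats::sd(x) / mean(x)))
  expect_lt(rsd(dc1$intensity), rsd(p1$intensity))
  # two batches with a step offset: QC medians agree within 5% after
  p2 <- gen_peaktable(d, n_features = 30, noise_sd = 0.1, n_batches = 2,
                      batch_shift = 1.5, qc_every = 4)
  dc2 <- drift_correct(p2)
  med_b <- function(tab, b) stats::median(tab$intensity[
    , tab$samples$role == "QC" & tab$samples$batch == b])
  expect_gt(med_b(p2, 2) / med_b(p2, 1), 2)        # step planted
  expect_lt(abs(med_b(dc2, 2) / med_b(dc2, 1) - 1), 0.05)
})

test_that("PQN: exact factors, idempotence, scale equivariance", {
  set.seed(9)
  ref <- 2^rnorm(50, 14, 2)
  I <- cbind(s1 = ref, s2 = 3 * ref, s3 = ref * 2^rnorm(50, 0, 0.1))
  rownames(I) <- sprintf("F%02d", 1:50)
  tab <- fix_peak_table(I)
  n <- pqn_normalize(tab, reference = "median")
  fac <- attr(n, "pqn_factors")
  # a pure 3x dilution of another sample differs by exactly that factor
  expect_equal(unname(fac["s2"] / fac["s1"]), 3, tolerance = 1e-12)
  expect_equal(n$intensity[, "s2"], n$intensity[, "s1"],
               ignore_attr = TRUE, tolerance = 1e-12)
  # idempotence: factors on PQN output are all 1
  n2 <- pqn_normalize(n, reference = "median")
  expect_true(all(abs(attr(n2, "pqn_factors") - 1) < 1e-9))
  # random table idempotence
  set.seed(19)
  R <- matrix(2^rnorm(50 * 8, 14, 1.5), 50,
              dimnames = list(sprintf("F%02d", 1:50),
                              sprintf("A-A_d2_r%d", 1:8)))
  nr <- pqn_normalize(fix_peak_table(R), reference = "median")
  nr2 <- pqn_normalize(nr, reference = "median")
  expect_true(all(abs(attr(nr2, "pqn_factors") - 1) < 1e-9))
  # scale equivariance against the QC reference (untouched by the
  # scaled biological sample): post-PQN values identical
  Iq <- cbind(I, QC1 = ref, QC2 = ref * 2^rnorm(50, 0, 0.05),
              QC3 = ref * 2^rnorm(50, 0, 0.05))
  tabq <- fix_peak_table(Iq, roles = c(rep("sample", 3), rep("QC", 3)))
  nq <- pqn_normalize(tabq, reference = "qc")
  tabq_s <- tabq; tabq_s$intensity[, "s3"] <- tabq_s$intensity[, "s3"] * 11
  nq2 <- pqn_normalize(tabq_s, reference = "qc")
  expect_equal(nq2$intensity, nq$intensity, tolerance = 1e-9)
  # a sample sharing nothing with the reference errors by name
  tab_na <- tab; tab_na$intensity[, "s3"] <- NA
  expect_error(pqn_normalize(tab_na, reference = "median"), "s3")
})

test_that("kNN imputation recovers a twin sample and beats the naive baseline", {
  set.seed(10)
  I <- matrix(2^rnorm(200, 14, 2), 20,
              dimnames = list(sprintf("F%02d", 1:20), NULL))
  I <- cbind(I, I[, 10])                       # duplicate a sample
  colnames(I) <- sprintf("A-A_d2_r%d", 1:11)
  tab <- fix_peak_table(I)
  # no missing cells: identity
  expect_identical(knn_impute(tab)$intensity, I)
  # one copy of the twin missing a feature: k=1 copies the twin's value
  tab$intensity[3, 11] <- NA
  imp <- knn_impute(tab, k = 1)
  expect_equal(imp$intensity[3, 11], I[3, 10])
  # mask-and-recover: median relative error < mean-imputation baseline
  d <- .mfx$d
  p <- gen_peaktable(d, n_features = 60, noise_sd = 0.3, seed = 12)
  truth <- p$intensity
  set.seed(13)
  mask <- which(matrix(runif(length(truth)) < 0.1, nrow(truth)))
  p$intensity[mask] <- NA
  imp2 <- knn_impute(p, k = 5)$intensity
  relerr <- function(est) stats::median(abs(est[mask] - truth[mask]) /
                                          truth[mask])
  # unimputed baseline: a single global constant for every missing cell
  base <- truth; base[mask] <- mean(p$intensity, na.rm = TRUE)
  expect_lt(relerr(imp2), relerr(base))
  expect_error(knn_impute(fix_peak_table(matrix(
    NA_real_, 1, 3, dimnames = list("F1", sprintf("A-A_d2_r%d", 1:3))))),
    "observed")
})

test_that("glog: lambda 0 is log2, monotone, and flattens an SD-mean trend", {
  I <- matrix(2^seq(2, 13, length.out = 12), 4,
              dimnames = list(paste0("F", 1:4), sprintf("A-A_d2_r%d", 1:3)))
  tab <- fix_peak_table(I)
  g0 <- glog_transform(tab, lambda = 0)
  expect_equal(g0$intensity, log2(I), ignore_attr = TRUE)
  expect_identical(attr(g0, "pre_glog"), I)
  x <- sort(runif(50, 0, 1e6))
  for (lam in c(0, 1, 1e4)) expect_true(all(diff(glog(x, lam)) > 0))
  expect_error(glog_transform(tab, lambda = -1), "lambda")
  # heteroscedastic table (SD proportional to mean): slope drops >= 50%
  set.seed(14)
  mu <- 2^runif(200, 8, 16)
  Q <- sapply(1:8, function(i) mu * (1 + rnorm(200, 0, 0.15)))
  Q[Q < 0] <- 0
  dimnames(Q) <- list(sprintf("F%03d", 1:200), sprintf("A-A_d2_r%d", 1:8))
  tabQ <- fix_peak_table(Q, roles = rep("QC", 8))
  slope <- function(M) {
    fm <- rowMeans(M); fs <- apply(M, 1, sd)
    unname(coef(lm(fs ~ fm))[2])
  }
  gq <- glog_transform(tabQ, lambda = "auto")
  expect_lt(abs(slope(gq$intensity)), 0.5 * abs(slope(log2(Q + 1))))
  expect_true(attr(gq, "glog_lambda") >= 0)
})

test_that("dual-contrast attribution recovers planted producers and rejects diffusion", {
  proc <- preprocess_peaks(.mfx$pt, drift = FALSE, group_peaks = FALSE)
  att <- attribute_producers(proc, "A", "C")
  expect_true(att$selected["F0001"])               # planted A-responds-to-C
  expect_false(att$selected["F0002"])              # diffusible: symmetric
  expect_lt(mean(att$selected), 0.05)
  # the mirrored question finds nothing (truth has no C-responds-to-A)
  att2 <- attribute_producers(proc, "C", "A")
  expect_false(any(att2$selected[c("F0001", "F0002")]))
  # invariant: padj >= p
  expect_true(all(att$stats$padj >= att$stats$p - 1e-15, na.rm = TRUE))
  # flat table: nothing selected
  set.seed(15)
  I <- matrix(2^rnorm(40 * 18, 14, 0.2), 40)
  dimnames(I) <- list(sprintf("F%02d", 1:40),
                      sprintf("%s_d%d_r%d",
                              rep(c("A-C", "A-A", "C-A"), each = 6),
                              rep(2:3, 9), rep(1:3, each = 2)))
  flat <- attribute_producers(fix_peak_table(I), "A", "C")
  expect_false(any(flat$selected))
  # missing condition group errors with the required groups listed
  sub <- .mfx$pt
  keep <- !(sub$samples$focal %in% "C" & sub$samples$partner %in% "A")
  sub2 <- peak_table(sub$intensity[, keep], sub$features,
                     sub$samples[keep, ])
  expect_error(attribute_producers(sub2, "A", "C"), "C-A")
})

test_that("a feature planted symmetrically in X-Y and Y-X is never selected", {
  # deterministic: identical group means give log2FC = 0 in the mirror
  # contrast, so the second comparison can never pass
  reps <- 4
  ids <- c(sprintf("A-C_d2_r%d", 1:reps), sprintf("A-A_d2_r%d", 1:reps),
           sprintf("C-A_d2_r%d", 1:reps), sprintf("C-C_d2_r%d", 1:reps))
  base <- 2^14
  I <- matrix(base, 2, length(ids),
              dimnames = list(c("Fsym", "Fctl"), ids))
  up <- grepl("^A-C|^C-A", ids)
  I["Fsym", up] <- base * 2^5                      # strong but symmetric
  I <- I * matrix(2^seq(-0.01, 0.01, length.out = length(I)), 2)
  att <- attribute_producers(fix_peak_table(I), "A", "C")
  expect_false(att$selected["Fsym"])
  att_m <- attribute_producers(fix_peak_table(I), "C", "A")
  expect_false(att_m$selected["Fsym"])
})

test_that("row Z-scoring matches hand computation and flags constant rows", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  z <- row_zscore(m)
  expect_equal(z["a", ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(z["b", ], c(0, 0, 0), ignore_attr = TRUE)
  expect_identical(attr(z, "constant_rows"), "b")
  set.seed(16)
  r <- matrix(rnorm(200), 10)
  rownames(r) <- paste0("g", 1:10)
  zr <- row_zscore(r)
  expect_true(all(abs(rowMeans(zr)) < 1e-12))
  expect_true(all(abs(apply(zr, 1, sd) - 1) < 1e-12))
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(3:200, 1))^sample(1:3, 1)
    expect_lt(max(abs(p.adjust(p, method = "BH") - bh_bruteforce(p))),
              1e-12)
  }
})

test_that("adduct masses match the published target ion and hand values", {
  # the printed DFO-B [M+2H]2+ target
  expect_identical(adduct_mz("C25H48N6O8", "[M+2H]2+"), 281.184)
  # hand: monoisotopic H2O = 18.0106, + proton 1.0073
  expect_identical(adduct_mz("H2O", "[M+H]+"), 19.018)
  # proton-mass property at 3 decimals for any formula
  for (f in c("C6H12O6", "C10H14N2", "CH4")) {
    expect_equal(round(adduct_mz(f, "[M+H]+", digits = Inf) -
                         monoisotopic_mass(f), 3), 1.007)
  }
  expect_equal(adduct_mz("C25H48N6O8", "[M-H]-"),
               round(monoisotopic_mass("C25H48N6O8") - 1.0072765, 3))
  expect_error(adduct_mz("C2Xx4", "[M+H]+"), "unknown element|parse")
  expect_error(adduct_mz("H2O", "[M+K]+"), "unsupported adduct")
})

test_that("targeted ion matching respects ppm tolerance and polarity", {
  I <- matrix(1000, 3, 3,
              dimnames = list(c("F1", "F2", "F3"),
                              sprintf("A-A_d2_r%d", 1:3)))
  tab <- fix_peak_table(I, mz = c(281.184, 282.184, 281.187))
  targets <- data.frame(name = "DFO-B", formula = "C25H48N6O8",
                        adducts = "[M+2H]2+", stringsAsFactors = FALSE)
  hit <- match_known_ions(tab, targets, tol_ppm = 10)
  expect_identical(hit$feature_id, "F1")           # F3 is ~11 ppm off
  # 1 Da away never matches at 10 ppm
  expect_false("F2" %in% hit$feature_id)
  # tighter tolerance drops a 5 ppm-off feature
  tab5 <- fix_peak_table(I[1, , drop = FALSE],
                         mz = 281.184 * (1 + 5e-6))
  expect_equal(nrow(match_known_ions(tab5, targets, tol_ppm = 0.1)), 0)
  # wrong polarity never matches
  tabneg <- tab; tabneg$features$polarity <- "-"
  expect_equal(nrow(match_known_ions(tabneg, targets, tol_ppm = 10)), 0)
})

test_that("preprocessing order is fixed and logged", {
  proc <- preprocess_peaks(.mfx$pt)
  steps <- vapply(proc$log, `[[`, "", "step")
  expect_identical(steps, c("gen_peaktable", "filter_features",
                            "group_related_peaks", "drift_correct",
                            "pqn_normalize", "knn_impute",
                            "glog_transform"))
})
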