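test_that("median-of-ratios size factors match the hand-computed example and invariants", {
  K <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  rownames(K) <- paste0("g", 1:3)
  # hand computation: geometric means (14.142, 28.284, 42.426); every
  # ratio in s1 is 1/sqrt(2), in s2 sqrt(2)
  expect_equal(unname(size_factors(K)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-6)
  expect_equal(unname(size_factors(K)), c(0.7071, 1.4142), tolerance = 1e-4)
  # identical samples -> all factors 1
  K2 <- cbind(a = c(5, 9, 14), b = c(5, 9, 14), c = c(5, 9, 14))
  rownames(K2) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(K2)), rep(1, 3))
  # scaling one sample by c multiplies its factor by c (equivariance),
  # and its normalized counts are unchanged
  set.seed(1)
  K3 <- matrix(rpois(60, 50) + 1, 10,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  s0 <- size_factors(K3)
  K3s <- K3; K3s[, 2] <- K3s[, 2] * 7
  s1 <- size_factors(K3s)
  expect_equal(unname(s1[2] / s0[2] / (s1[1] / s0[1])), 7, tolerance = 1e-12)
  n0 <- normalized_counts(K3); n1 <- normalized_counts(K3s)
  expect_equal(n1[, 2] / n1[, 1], n0[, 2] / n0[, 1], tolerance = 1e-12)
  # no gene nonzero everywhere -> instructive error; pseudo-reference works
  K4 <- cbind(a = c(5, 0), b = c(0, 7))
  rownames(K4) <- c("g1", "g2")
  expect_error(size_factors(K4), "pseudo_reference")
  expect_length(size_factors(K4, pseudo_reference = TRUE), 2)
})

test_that("TPM matches hand examples and columns sum to 1e6", {
  K <- cbind(s1 = c(10, 20))
  rownames(K) <- c("g1", "g2")
  expect_equal(unname(tpm(K, c(g1 = 1000, g2 = 2000))[, 1]), c(5e5, 5e5))
  K1 <- cbind(s1 = 17); rownames(K1) <- "g1"
  expect_equal(unname(tpm(K1, c(g1 = 500))[, 1]), 1e6)
  set.seed(2)
  Kr <- matrix(rpois(80, 30), 10,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  L <- stats::setNames(sample(200:2000, 10), rownames(Kr))
  tp <- tpm(Kr, L)
  expect_true(all(abs(colSums(tp) - 1e6) < 1e6 * 1e-6))
  Kz <- Kr; Kz[, 3] <- 0
  expect_identical(attr(tpm(Kz, L), "zero_columns"), "s3")
  expect_error(tpm(Kr, L[-1]), "lengths")
})

test_that("Wald NB test recovers a planted 4x effect and nulls identical groups", {
  set.seed(7)
  ng <- 300
  K <- matrix(rnbinom(ng * 6, mu = 500, size = 20), ng,
              dimnames = list(paste0("g", seq_len(ng)), paste0("s", 1:6)))
  planted <- 1:10                                   # planted log2FC = 2
  K[planted, 4:6] <- rnbinom(3 * length(planted), mu = 2000, size = 20)
  de <- differential_expression(K, mode = "wald",
                                group = rep(c("ctl", "trt"), each = 3),
                                ref = "ctl")
  expect_lt(abs(stats::median(de$log2FC[planted]) - 2), 0.3)
  expect_true(all(de$padj[planted] <= 0.05))
  # invariants: padj >= p, padj in [0, 1]
  ok <- !is.na(de$padj)
  expect_true(all(de$padj[ok] >= de$pvalue[ok]))
  expect_true(all(de$padj[ok] >= 0 & de$padj[ok] <= 1))
  # identical groups (columns duplicated): log2FC exactly 0
  K2 <- K[, c(1:3, 1:3)]
  colnames(K2) <- paste0("s", 1:6)
  de2 <- differential_expression(K2, mode = "wald",
                                 group = rep(c("a", "b"), each = 3),
                                 ref = "a")
  expect_true(all(abs(de2$log2FC[de2$tested]) < 1e-8))
  # zero-variance gene is excluded from testing
  K3 <- K; K3[2, ] <- 50
  de3 <- differential_expression(K3, mode = "wald",
                                 group = rep(c("a", "b"), each = 3))
  expect_false(de3$tested[2])
  # independent-filtering floor: low-baseMean genes carry padj NA
  K4 <- K; K4[3, ] <- c(1, 0, 0, 0, 0, 1)
  de4 <- differential_expression(K4, mode = "wald",
                                 group = rep(c("a", "b"), each = 3),
                                 min_base_mean = 1)
  expect_true(is.na(de4$padj[3]))
  expect_error(differential_expression(K, mode = "wald",
                                       group = rep(c("a", "b", "c"), 2)),
               "two groups")
})

test_that("LRT detects a partner-by-day interaction and not a flat gene", {
  d <- fix_design(strains = c("A", "C"), days = 2:3, replicates = 3)
  samp <- d$samples[d$samples$focal == "A", ]
  set.seed(11)
  ng <- 60
  K <- sapply(seq_len(nrow(samp)), function(j) rnbinom(ng, mu = 300, size = 20))
  dimnames(K) <- list(paste0("g", seq_len(ng)), samp$sample_id)
  hit <- samp$partner == "C" & samp$day == 3
  K[1, hit] <- rnbinom(sum(hit), mu = 300 * 8, size = 20)
  lrt <- differential_expression(K, samples = samp, mode = "lrt")
  expect_lt(lrt$pvalue[1], 1e-4)
  expect_gt(min(lrt$pvalue[-1], na.rm = TRUE), 1e-4)
  expect_identical(attr(lrt, "mode"), "lrt")
})

test_that("multiplexing fidelity: concatenated arm reproduces singleplex counts", {
  d <- fix_design(days = 4, replicates = 2)
  g <- fix_genomes(d, shared_fraction = 0)
  idx <- build_reference_index(g)
  smp <- d$samples$sample_id[d$samples$partner == "B" &
                               d$samples$day == 4]
  rd <- gen_reads(g, d, depth = 50, read_len = 60, samples = smp)
  sets <- split(smp, sub(".*_r", "", smp))   # 4 focal strains per library
  mf <- multiplex_fidelity(rd, sets, idx, d)
  expect_true(mf$identical_counts)
  expect_equal(mf$r, 1)
  expect_equal(mf$n_de, 0)
  expect_error(multiplex_fidelity(rd, list(), idx, d), "empty")
  expect_error(multiplex_fidelity(rd, sets[1], idx, d), "differs")
})

test_that("multiplexing with shared genes loses them to AMBIGUOUS identically in both arms", {
  d <- fix_design(days = 4, replicates = 2)
  g <- fix_genomes(d, shared_fraction = 0.25, n_genes = 8)
  idx <- build_reference_index(g)
  smp <- d$samples$sample_id[d$samples$partner == "B" & d$samples$day == 4]
  rd <- gen_reads(g, d, depth = 50, read_len = 60, samples = smp, seed = 4)
  mf <- multiplex_fidelity(rd, split(smp, sub(".*_r", "", smp)), idx, d)
  uniq <- !grepl("_s", rownames(mf$single$counts))
  expect_identical(mf$single$counts[uniq, smp], mf$multi$counts[uniq, smp])
  # unique-gene counts equal generator truth
  expect_equal(mf$single$counts[uniq, smp],
               rd$truth_counts[uniq, smp], ignore_attr = TRUE)
  # shared genes draw zero counts in both arms (discarded as ambiguous)
  expect_true(all(mf$single$counts[!uniq, ] == 0))
  expect_true(all(mf$multi$counts[!uniq, ] == 0))
})
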