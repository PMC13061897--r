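test_that("design validates and labels follow the focal-partner convention", {
  d <- fix_design(strains = c("A", "C"), days = 2:3, replicates = 2)
  expect_equal(nrow(d$samples), 2 * 2 * 2 * 2)
  expect_true(all(grepl("^[A-Z]-[A-Z]_d[0-9]+_r[0-9]+$", d$samples$sample_id)))
  expect_error(synth_design(strains = c("A", "A")), "unique")
  expect_error(synth_design(replicates = 1), ">= 2")
  expect_error(planted_truth(producer_features = data.frame(
    feature_id = "F0001", producer = "A", responder = NA, lfc = 0,
    diffusible = FALSE)), "nonzero")
})

test_that("genome generator packs genes, shares the stated fraction, and is byte-deterministic", {
  d <- fix_design()
  expect_error(gen_genomes(d, genome_len = 1000, n_genes = 20,
                           gene_len = 400), "packing")
  g <- gen_genomes(d, genome_len = 20000, n_genes = 20, gene_len = 400,
                   shared_fraction = 0.5)
  ann <- g$annotation
  # exactly 10 shared genes per strain, byte-identical across strains
  expect_equal(unname(table(ann$shared, ann$strain)["TRUE", ]),
               rep(10, 4), ignore_attr = TRUE)
  for (b in unique(ann$base_id[ann$shared])) {
    seqs <- g$gene_seqs[ann$gene_id[ann$base_id == b]]
    expect_length(unique(unname(seqs)), 1)
  }
  # annotation consistent with the genome: gene sequence found at coords
  i <- which(!ann$shared)[1]
  sub <- substr(g$genomes[[ann$strain[i]]], ann$start[i], ann$end[i])
  expected <- if (ann$strand[i] == "+") g$gene_seqs[[ann$gene_id[i]]]
              else as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(g$gene_seqs[[ann$gene_id[i]]])))
  expect_identical(sub, expected)
  # same seed twice -> byte-identical FASTA files
  g2 <- gen_genomes(d, genome_len = 20000, n_genes = 20, gene_len = 400,
                    shared_fraction = 0.5)
  d1 <- file.path(tempdir(), "gen1"); d2 <- file.path(tempdir(), "gen2")
  write_genomes(g, d1); write_genomes(g2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("read simulator hits expected depth, planted effects, and concatenation conservation", {
  d <- fix_design(strains = c("A", "C"), days = 4, replicates = 2)
  g <- fix_genomes(d, n_genes = 2, gene_len = 400, genome_len = 4000)
  tr <- planted_truth(de_genes = data.frame(
    gene_id = "A_u01", strain = "A", partner = "C", day_min = 4,
    day_max = 4, lfc = 2))
  rd <- gen_reads(g, d, tr, depth = 100, read_len = 75)
  # no planted DE in A-A: both genes ~ Poisson(100)
  aa <- rd$truth_counts[c("A_u01", "A_u02"), "A-A_d4_r1"]
  expect_true(all(aa >= qpois(0.0005, 100) & aa <= qpois(0.9995, 100)))
  # planted log2FC +2 in A-C: ratio vs A-A near 4x at matched depth
  ac <- mean(rd$truth_counts["A_u01", c("A-C_d4_r1", "A-C_d4_r2")])
  aa2 <- mean(rd$truth_counts["A_u01", c("A-A_d4_r1", "A-A_d4_r2")])
  expect_gt(ac / aa2, 2.5)
  expect_lt(ac / aa2, 6)
  # reads drawn from gene bodies only; names carry true origin
  expect_true(all(read_truth(rd$reads[["A-C_d4_r1"]])$strain == "A"))
  # multiplexed library = concatenation of member samples
  mux <- multiplex_reads(rd, list(lib1 = c("A-C_d4_r1", "C-A_d4_r1")))
  expect_equal(nrow(mux$lib1), nrow(rd$reads[["A-C_d4_r1"]]) +
                 nrow(rd$reads[["C-A_d4_r1"]]))
  expect_error(multiplex_reads(rd, list()), "empty")
  expect_error(multiplex_reads(rd, list(lib1 = character(0))), "empty")
  expect_error(gen_reads(g, d, depth = 100, read_len = 500), "read_len")
})

test_that("peak-table generator plants effects, places QCs, and calibrates missingness", {
  d <- synth_design(seed = 7)   # full 4x4x5x3 design
  tr <- planted_truth(producer_features = data.frame(
    feature_id = c("F0001", "F0002"), producer = c("C", "A"),
    responder = c(NA, "C"), lfc = c(4, 3), diffusible = c(TRUE, FALSE),
    mz = c(281.184, NA)))
  pt <- gen_peaktable(d, tr, n_features = 1000, missing_rate = 0.2,
                      qc_every = 6)
  # overall missing fraction within 2% (relative) of the target
  expect_lt(abs(mean(is.na(pt$intensity)) - 0.2), 0.004)
  # planted truth completeness: every planted id is in the table
  expect_true(all(tr$producer_features$feature_id %in%
                    rownames(pt$intensity)))
  expect_equal(pt$features$mz[1], 281.184)
  # QCs at every 6th biological injection within a batch
  sm <- pt$samples
  expect_true(all(diff(which(sm$role == "QC")) == 7))
  # diffusible feature elevated in C-* focal AND *-C partner samples
  E <- attr(pt, "expected_log2")
  bio <- d$samples
  elev <- E["F0001", ] - stats::median(E["F0001", ])
  expect_equal(unname(elev > 2), bio$focal == "C" | bio$partner == "C")
  # induced non-diffusible feature elevated only in A-C
  elev2 <- E["F0002", ] - stats::median(E["F0002", ])
  expect_equal(unname(elev2 > 2), bio$focal == "A" & bio$partner == "C")
  expect_error(gen_peaktable(d, tr, n_features = 1), "cover")
  expect_error(gen_peaktable(d, qc_every = 1), "qc_every")
})

test_that("peak-table generator is deterministic and QCs are pooled-mean replicates", {
  d <- fix_design(strains = c("A", "C"), days = 2:3)
  p1 <- gen_peaktable(d, n_features = 50)
  p2 <- gen_peaktable(d, n_features = 50)
  expect_identical(p1$intensity, p2$intensity)
  # with zero noise and no drift, all QC injections are identical
  p0 <- gen_peaktable(d, n_features = 50, noise_sd = 0)
  qc <- p0$intensity[, p0$samples$role == "QC", drop = FALSE]
  expect_true(all(apply(qc, 1, function(x) diff(range(x))) < 1e-9))
})

test_that("plate-image generator records analytic truth and flags overlap", {
  pl <- gen_plate_image(300, 300, data.frame(cx = 150, cy = 150, radius = 50))
  expect_equal(pl$truth$area_px, pi * 50^2, tolerance = 1e-12)
  empty <- gen_plate_image(200, 200)
  expect_equal(nrow(empty$truth), 0)
  # only background and rim grey levels (plus noise)
  expect_lt(max(empty$image), 0.7)
  two <- gen_plate_image(300, 300, data.frame(cx = c(80, 200), cy = 150,
                                              radius = c(20, 40)))
  expect_equal(two$truth$radius, c(40, 20))        # sorted by area desc
  expect_false(any(two$truth$overlapping))
  ovl <- gen_plate_image(300, 300, data.frame(cx = c(140, 160), cy = 150,
                                              radius = c(30, 30)))
  expect_true(all(ovl$truth$overlapping))
  expect_error(gen_plate_image(200, 200, data.frame(cx = 10, cy = 10,
                                                    radius = 30)),
               "inside the plate")
})

test_that("annotation generator yields reproducible, disjoint-when-possible pathways", {
  a1 <- gen_annotation(200, n_pathways = 5, genes_per_pathway = 10, seed = 3)
  a2 <- gen_annotation(200, n_pathways = 5, genes_per_pathway = 10, seed = 3)
  expect_identical(a1, a2)
  expect_true(all(table(a1$gene2ko$gene_id) == 1))      # <= 1 KO per gene
  sizes <- table(a1$ko2path$pathway)
  expect_true(all(sizes == 10))
  expect_false(anyDuplicated(a1$ko2path$ko) > 0)        # disjoint here
  expect_error(gen_annotation(50, 2, 0), "genes_per_pathway")
})

test_that("image round trip preserves content (PGM text and PNG)", {
  img <- matrix(seq(0, 1, length.out = 30 * 20), nrow = 20)
  for (ext in c("pgm", "png")) {
    p <- file.path(tempdir(), paste0("img.", ext))
    write_image(img, p)
    back <- read_image(p)
    expect_equal(dim(back), dim(img))
    expect_lt(max(abs(back - img)), 1 / 254)
  }
})
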