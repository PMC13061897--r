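# Shared fixtures, built in code. Kept deliberately small; heavier
# simulations live in the tests that need them.

fix_design <- function(strains = c("A", "B", "C", "D"), days = 2:4,
                       replicates = 3, seed = 101) {
  synth_design(strains = strains, days = days, replicates = replicates,
               seed = seed)
}

fix_genomes <- function(design = fix_design(), shared_fraction = 0,
                        n_genes = 8, gene_len = 400, genome_len = 15000) {
  gen_genomes(design, genome_len = genome_len, n_genes = n_genes,
              gene_len = gene_len, shared_fraction = shared_fraction)
}

# decompose read ids "sample|strain|gene|i" into truth columns
read_truth <- function(reads) {
  parts <- strsplit(reads$id, "|", fixed = TRUE)
  data.frame(sample = vapply(parts, `[`, "", 1),
             strain = vapply(parts, `[`, "", 2),
             gene = vapply(parts, `[`, "", 3), stringsAsFactors = FALSE)
}

# independent step-up BH oracle
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# minimal hand-built peak table: intensities I (features x samples),
# condition labels parsed from column names "X-Y_dD_rR" (role sample);
# extra QC/blank columns can be appended via roles.
fix_peak_table <- function(I, mz = NULL, rt = NULL, roles = NULL) {
  fid <- rownames(I)
  feats <- data.frame(feature_id = fid,
                      mz = mz %||% seq(100, 100 + nrow(I) - 1),
                      rt = rt %||% seq(100, 100 + 10 * (nrow(I) - 1), by = 10),
                      polarity = "+", stringsAsFactors = FALSE)
  ids <- colnames(I)
  roles <- roles %||% rep("sample", ncol(I))
  parse <- function(id, field) {
    m <- regmatches(id, regexec("^([A-Z])-([A-Z])_d([0-9]+)_r([0-9]+)$", id))[[1]]
    if (length(m) == 0)           # unlabelled fixture column: dummy axenic
      return(switch(field, focal = "A", partner = "A", day = 2L,
                    replicate = 1L))
    switch(field, focal = m[2], partner = m[3], day = as.integer(m[4]),
           replicate = as.integer(m[5]))
  }
  samples <- data.frame(
    sample_id = ids,
    focal = vapply(ids, parse, "", field = "focal"),
    partner = vapply(ids, parse, "", field = "partner"),
    day = vapply(ids, function(i) as.integer(parse(i, "day")), 1L),
    replicate = vapply(ids, function(i) as.integer(parse(i, "replicate")), 1L),
    injection_order = seq_along(ids), batch = 1L, role = roles,
    stringsAsFactors = FALSE)
  samples$focal[roles != "sample"] <- NA
  samples$partner[roles != "sample"] <- NA
  peak_table(I, feats, samples)
}
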