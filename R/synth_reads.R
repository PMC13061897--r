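#' Simulate RNA-seq reads per sample, with optional multiplexing
#'
#' Draws error-free (by default) fixed-length reads uniformly from gene
#' bodies of each sample's focal strain, with per-gene expected counts
#' `depth * 2^lfc` where `lfc` comes from the planted differential
#' expression truth (zero otherwise), plus a stated fraction of reads from
#' the strain's rRNA-like sequence. Gene counts are Poisson. Read names
#' encode the true origin (`sample|strain|gene|i`) so assignment can be
#' checked against truth. Each sample's reads are generated under a child
#' seed derived from (seed, sample index), so a multiplexed library built
#' later by [multiplex_reads()] is exactly the concatenation of its member
#' samples' singleplex reads.
#'
#' @param genomes a [gen_genomes()] result.
#' @param design a [synth_design()].
#' @param truth a [planted_truth()] (only `de_genes` is used here).
#' @param depth expected reads per gene at baseline.
#' @param read_len read length (bp), must be < gene length.
#' @param rrna_fraction expected fraction of each library drawn from rRNA.
#' @param error_rate per-base substitution probability (default 0, keeping
#'   the exact-k-mer assigner's oracle clean).
#' @param samples sample ids to simulate (default: all in the design).
#' @param seed base RNG seed; defaults to the design seed.
#' @return class `synth_reads`: `reads` (named list of data frames with
#'   columns id, seq), `truth_counts` (gene x sample matrix of true
#'   gene-body read counts), `rrna_counts` (per sample), `params`.
#' @export
gen_reads <- function(genomes, design, truth = planted_truth(),
                      depth = 100, read_len = 75L, rrna_fraction = 0,
                      error_rate = 0, samples = NULL, seed = design$seed) {
  ann <- genomes$annotation
  if (read_len >= min(ann$length))
    stopf("read_len (%d) must be < min gene length (%d)", read_len, min(ann$length))
  if (depth < 1) stopf("depth must be >= 1")
  samples <- samples %||% design$samples$sample_id
  smeta <- design$samples[match(samples, design$samples$sample_id), ]
  if (anyNA(smeta$focal)) stopf("unknown sample id(s)")
  de <- truth$de_genes
  genes_all <- ann$gene_id
  truth_counts <- matrix(0L, nrow = length(genes_all), ncol = length(samples),
                         dimnames = list(genes_all, samples))
  rrna_counts <- stats::setNames(integer(length(samples)), samples)
  reads <- vector("list", length(samples)); names(reads) <- samples
  sim_one <- function(sm) {
    g_ann <- ann[ann$strain == sm$focal, ]
    lam <- rep(depth, nrow(g_ann))
    if (nrow(de)) {
      hit <- match(g_ann$gene_id, de$gene_id)
      ok <- !is.na(hit) & de$strain[hit] == sm$focal &
        de$partner[hit] == sm$partner &
        sm$day >= de$day_min[hit] & sm$day <= de$day_max[hit]
      lam[ok] <- depth * 2^de$lfc[hit[ok]]
    }
    cnt <- stats::rpois(nrow(g_ann), lam)
    n_rrna <- if (rrna_fraction > 0)
      stats::rpois(1, rrna_fraction / (1 - rrna_fraction) * sum(cnt)) else 0L
    origin <- c(rep(g_ann$gene_id, cnt), rep("rrna", n_rrna))
    src <- c(rep(genomes$gene_seqs[g_ann$gene_id], cnt),
             rep(genomes$rrna[[sm$focal]], n_rrna))
    n <- length(src)
    if (n == 0L) {
      df <- data.frame(id = character(), seq = character(),
                       stringsAsFactors = FALSE)
    } else {
      starts <- floor(stats::runif(n, 1, nchar(src) - read_len + 2))
      sq <- substr(src, starts, starts + read_len - 1L)
      flip <- stats::runif(n) < 0.5
      if (any(flip)) sq[flip] <- revcomp(sq[flip])
      if (error_rate > 0) {
        nerr <- stats::rbinom(n, read_len, error_rate)
        for (j in which(nerr > 0)) {
          pos <- sample(read_len, nerr[j])
          s <- strsplit(sq[j], "")[[1]]
          s[pos] <- sample(c("A", "C", "G", "T"), nerr[j], replace = TRUE)
          sq[j] <- paste(s, collapse = "")
        }
      }
      df <- data.frame(id = sprintf("%s|%s|%s|%d", sm$sample_id, sm$focal,
                                    origin, seq_len(n)),
                       seq = sq, stringsAsFactors = FALSE)
    }
    list(df = df, genes = g_ann$gene_id, cnt = cnt, n_rrna = n_rrna)
  }
  for (i in seq_along(samples)) {
    sm <- smeta[i, ]
    sidx <- match(sm$sample_id, design$samples$sample_id)
    res <- with_seed(child_seed(seed, sidx), sim_one(sm))
    truth_counts[res$genes, i] <- res$cnt
    rrna_counts[i] <- res$n_rrna
    reads[[i]] <- res$df
  }
  structure(list(reads = reads, truth_counts = truth_counts,
                 rrna_counts = rrna_counts,
                 params = list(depth = depth, read_len = read_len,
                               rrna_fraction = rrna_fraction,
                               error_rate = error_rate, seed = seed)),
            class = "synth_reads")
}

#' Concatenate singleplex samples into multiplexed libraries
#'
#' A multiplexed library is the plain concatenation of its member samples'
#' reads, mirroring pooling of RNA samples before library preparation.
#'
#' @param reads a [gen_reads()] result.
#' @param sets list of character vectors of sample ids; each set becomes
#'   one library. Empty sets are an error.
#' @return named list of read data frames (id, seq), one per library.
#' @export
multiplex_reads <- function(reads, sets) {
  if (length(sets) == 0L) stopf("empty multiplex list")
  if (is.null(names(sets)))
    names(sets) <- sprintf("mux%02d", seq_along(sets))
  lapply(stats::setNames(names(sets), names(sets)), function(nm) {
    members <- sets[[nm]]
    if (length(members) == 0L) stopf("empty multiplex set '%s'", nm)
    miss <- setdiff(members, names(reads$reads))
    if (length(miss)) stopf("unknown sample(s) in multiplex set: %s",
                            paste(miss, collapse = ", "))
    do.call(rbind, reads$reads[members])
  })
}

#' Write reads to FASTQ
#'
#' Constant placeholder qualities ("I" = Q40) are written; the synthetic
#' reads carry no quality model.
#'
#' @param lib data frame with columns id, seq.
#' @param path output path (uncompressed FASTQ).
#' @export
write_fastq <- function(lib, path) {
  x <- Biostrings::DNAStringSet(lib$seq)
  names(x) <- lib$id
  q <- Biostrings::BStringSet(strrep("I", nchar(lib$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into the package's read table
#' @param path FASTQ path.
#' @return data frame with columns id, seq.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = names(x), seq = as.character(x), stringsAsFactors = FALSE)
}
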