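#' Build a k-mer reference index over concatenated strain genomes
#'
#' The index holds, per strain, every distinct forward-strand genome k-mer
#' with its first occurrence position, plus a both-strand k-mer set for the
#' rRNA sequences, and the gene annotation. It backs the competitive read
#' assigner that stands in for alignment against the concatenated genomes:
#' deterministic, exact, and faithful to the discard-ambiguous contract.
#'
#' @param genomes a [gen_genomes()] result, or a list with `genomes`
#'   (named character), `rrna` (named character) and `annotation`
#'   (data frame with gene_id, strain, start, end, strand, length;
#'   1-based inclusive coordinates).
#' @param k k-mer length (>= 11).
#' @return object of class `reference_index`.
#' @export
build_reference_index <- function(genomes, k = 21L) {
  if (k < 11) stopf("k must be >= 11")
  ann <- genomes$annotation
  gl <- nchar(genomes$genomes)
  bad <- ann$end > gl[ann$strain] | ann$start < 1
  if (any(bad)) stopf("annotated gene(s) outside genome bounds: %s",
                      paste(ann$gene_id[bad], collapse = ", "))
  strains <- names(genomes$genomes)
  idx <- lapply(genomes$genomes, function(g) {
    n <- nchar(g)
    km <- substring(g, seq_len(n - k + 1L), seq.int(k, n))
    keep <- !duplicated(km)
    list(kmers = km[keep], pos = which(keep))
  })
  rk <- unlist(lapply(c(genomes$rrna, revcomp(genomes$rrna)), function(r) {
    n <- nchar(r)
    substring(r, seq_len(n - k + 1L), seq.int(k, n))
  }), use.names = FALSE)
  structure(list(strains = strains, k = as.integer(k), index = idx,
                 rrna_kmers = unique(rk), annotation = ann),
            class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("reference_index: %d strains, k=%d, %d genes, %d rRNA k-mers\n",
              length(x$strains), x$k, nrow(x$annotation),
              length(x$rrna_kmers)))
  invisible(x)
}

# k-mer matrix (reads x positions) for equal-length reads; ragged reads
# are handled by padding groups per length.
read_kmers <- function(seqs, k) {
  lens <- nchar(seqs)
  if (length(unique(lens)) == 1L && lens[1] >= k) return(kmerize_equal(seqs, k))
  nk <- max(lens) - k + 1L
  m <- matrix(NA_character_, nrow = length(seqs), ncol = max(nk, 1L))
  for (j in seq_len(max(nk, 1L))) {
    ok <- lens >= j + k - 1L
    m[ok, j] <- substr(seqs[ok], j, j + k - 1L)
  }
  m
}

#' Remove rRNA reads by k-mer content
#'
#' The in-silico analogue of an rRNA decontamination pass: a read is
#' removed iff at least `min_kmer_fraction` of its k-mers occur in the
#' rRNA k-mer set (both strands are in the set, so one forward pass over
#' the read suffices). Reads shorter than k cannot be classified; they are
#' retained and counted.
#'
#' @param reads data frame with columns id, seq.
#' @param index a [build_reference_index()].
#' @param min_kmer_fraction fraction in (0, 1].
#' @return list: `retained` (read data frame), `n_removed`,
#'   `n_unclassifiable`.
#' @export
filter_rrna <- function(reads, index, min_kmer_fraction = 0.5) {
  if (nrow(reads) == 0L) stopf("reads must be non-empty")
  if (min_kmer_fraction <= 0 || min_kmer_fraction > 1)
    stopf("min_kmer_fraction must be in (0, 1]")
  k <- index$k
  short <- nchar(reads$seq) < k
  hit_frac <- rep(0, nrow(reads))
  if (any(!short)) {
    km <- read_kmers(reads$seq[!short], k)
    hits <- matrix(km %in% index$rrna_kmers & !is.na(km), nrow = nrow(km))
    nkm <- rowSums(!is.na(km))
    hit_frac[!short] <- rowSums(hits) / nkm
  }
  drop <- !short & hit_frac >= min_kmer_fraction
  list(retained = reads[!drop, , drop = FALSE],
       n_removed = sum(drop), n_unclassifiable = sum(short))
}

#' Competitively assign reads to strains
#'
#' Per strain, the score is the number of read k-mers found in that
#' strain's genome (forward and reverse-complement orientations scored
#' separately, the larger taken). A read is assigned to the unique strain
#' with strictly maximal score at or above `min_match_frac` of its
#' k-mers; ties across two or more strains at the top give `AMBIGUOUS`
#' (discarded downstream, as for ambiguous matches across concatenated
#' genomes); a top score below threshold gives `UNMAPPED`. For assigned
#' reads the anchor is the genome position of the first matching k-mer,
#' used for gene-overlap counting.
#'
#' @param reads data frame with columns id, seq.
#' @param index a [build_reference_index()].
#' @param min_match_frac minimum fraction of a read's k-mers that must
#'   match the winning strain.
#' @return data frame: id, assignment (strain, "AMBIGUOUS" or
#'   "UNMAPPED"), anchor_pos (NA unless assigned), orientation, score.
#' @export
assign_reads <- function(reads, index, min_match_frac = 0.5) {
  n <- nrow(reads)
  strains <- index$strains
  out <- data.frame(id = reads$id,
                    assignment = rep("UNMAPPED", n),
                    anchor_pos = rep(NA_integer_, n),
                    orientation = rep(NA_character_, n),
                    score = rep(0L, n), stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  k <- index$k
  usable <- nchar(reads$seq) >= k
  if (!any(usable)) return(out)
  seqs <- reads$seq[usable]
  km_f <- read_kmers(seqs, k)
  km_r <- read_kmers(revcomp(seqs), k)
  nkm <- rowSums(!is.na(km_f))
  nr <- length(seqs)
  scores <- matrix(0L, nr, length(strains), dimnames = list(NULL, strains))
  orient <- matrix("fwd", nr, length(strains))
  mi <- vector("list", length(strains)); names(mi) <- strains
  for (s in strains) {
    si <- match(s, strains)
    mf <- matrix(match(km_f, index$index[[s]]$kmers), nrow = nr)
    mr <- matrix(match(km_r, index$index[[s]]$kmers), nrow = nr)
    cf <- rowSums(!is.na(mf)); cr <- rowSums(!is.na(mr))
    use_r <- cr > cf
    scores[, s] <- ifelse(use_r, cr, cf)
    orient[, si] <- ifelse(use_r, "rev", "fwd")
    best <- mf; best[use_r, ] <- mr[use_r, ]
    mi[[s]] <- best
  }
  top <- apply(scores, 1, max)
  n_top <- rowSums(scores == top)
  pass <- top >= pmax(1, ceiling(min_match_frac * nkm))
  asg <- rep("UNMAPPED", nr)
  asg[pass & n_top >= 2] <- "AMBIGUOUS"
  winner <- pass & n_top == 1
  ws <- strains[max.col(scores, ties.method = "first")]
  asg[winner] <- ws[winner]
  anchor <- rep(NA_integer_, nr); ori <- rep(NA_character_, nr)
  for (s in strains) {
    rows <- which(winner & ws == s)
    if (!length(rows)) next
    m <- mi[[s]][rows, , drop = FALSE]
    j <- apply(!is.na(m), 1, which.max)        # first matching k-mer
    anchor[rows] <- index$index[[s]]$pos[m[cbind(seq_along(rows), j)]]
    ori[rows] <- orient[rows, match(s, strains)]
  }
  out$assignment[usable] <- asg
  out$anchor_pos[usable] <- anchor
  out$orientation[usable] <- ori
  out$score[usable] <- top
  out
}

#' Count assigned reads into genes by anchor overlap
#'
#' A read increments gene i iff its anchor position falls inside gene i's
#' interval on the assigned strain (strand-agnostic). A read whose anchor
#' overlaps two genes is credited to the gene covering the anchor with the
#' smallest start (deterministic tie-break). Reads overlapping no gene go
#' to a per-library "intergenic" sink.
#'
#' @param assignments result of [assign_reads()].
#' @param index a [build_reference_index()].
#' @return list: `counts` (named integer vector over all annotated
#'   genes), `intergenic` (count).
#' @export
count_genes <- function(assignments, index) {
  ann <- index$annotation
  counts <- stats::setNames(integer(nrow(ann)), ann$gene_id)
  asg <- assignments[assignments$assignment %in% index$strains, , drop = FALSE]
  intergenic <- 0L
  for (s in unique(asg$assignment)) {
    a <- asg[asg$assignment == s, ]
    g <- ann[ann$strain == s, ]
    g <- g[order(g$start), ]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = a$anchor_pos, width = 1L),
      IRanges::IRanges(start = g$start, end = g$end),
      select = "first")
    hit <- !is.na(ov)
    tab <- table(g$gene_id[ov[hit]])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    intergenic <- intergenic + sum(!hit)
  }
  list(counts = counts, intergenic = intergenic)
}

#' Deconvolve a set of (possibly multiplexed) libraries into gene counts
#'
#' Runs the full per-library chain — rRNA decontamination, competitive
#' strain assignment, anchor-overlap gene counting — and, when the
#' library-to-sample mapping is given, demultiplexes library counts into
#' per-sample columns: sample "X-Y" receives the counts of strain X's
#' genes from its library. Samples multiplexed in one library must have
#' distinct focal strains (that is what makes deconvolution possible).
#'
#' @param libraries named list of read data frames (id, seq).
#' @param index a [build_reference_index()].
#' @param design a [synth_design()]; required when `lib_samples` is given.
#' @param lib_samples named list mapping library name -> sample ids it
#'   multiplexes; NULL treats each library as one column.
#' @param min_kmer_fraction rRNA filter threshold, see [filter_rrna()].
#' @param min_match_frac assignment threshold, see [assign_reads()].
#' @return object of class `count_matrix`: `counts` (gene x column
#'   integer matrix), `gene_lengths`, `samples` (column metadata),
#'   `accounting` (per library: total, rrna, per-strain assigned,
#'   ambiguous, unmapped, unclassifiable, intergenic).
#' @export
deconvolve_libraries <- function(libraries, index, design = NULL,
                                 lib_samples = NULL,
                                 min_kmer_fraction = 0.5,
                                 min_match_frac = 0.5) {
  if (length(libraries) == 0L) stopf("no libraries given")
  ann <- index$annotation
  acc <- list(); lib_counts <- list(); lib_strain_counts <- list()
  for (nm in names(libraries)) {
    lib <- libraries[[nm]]
    fr <- filter_rrna(lib, index, min_kmer_fraction)
    asg <- assign_reads(fr$retained, index, min_match_frac)
    cg <- count_genes(asg, index)
    lib_counts[[nm]] <- cg$counts
    tab <- table(factor(asg$assignment,
                        levels = c(index$strains, "AMBIGUOUS", "UNMAPPED")))
    acc[[nm]] <- data.frame(library = nm, total = nrow(lib),
                            rrna = fr$n_removed,
                            unclassifiable = fr$n_unclassifiable,
                            t(as.matrix(tab)), intergenic = cg$intergenic,
                            check.names = FALSE, stringsAsFactors = FALSE)
  }
  accounting <- do.call(rbind, acc)
  rownames(accounting) <- NULL
  if (is.null(lib_samples)) {
    counts <- do.call(cbind, lib_counts)
    colnames(counts) <- names(libraries)
    samples <- data.frame(sample_id = names(libraries), focal = NA,
                          partner = NA, day = NA, replicate = NA,
                          library = names(libraries), stringsAsFactors = FALSE)
  } else {
    if (is.null(design)) stopf("design is required to demultiplex")
    cols <- list(); meta <- list()
    for (nm in names(lib_samples)) {
      sids <- lib_samples[[nm]]
      sm <- design$samples[match(sids, design$samples$sample_id), ]
      if (anyNA(sm$focal)) stopf("unknown sample id in library %s", nm)
      if (anyDuplicated(sm$focal))
        stopf("library %s multiplexes two samples with the same focal strain; cannot deconvolve", nm)
      for (i in seq_along(sids)) {
        v <- stats::setNames(integer(nrow(ann)), ann$gene_id)
        mine <- ann$strain == sm$focal[i]
        v[mine] <- lib_counts[[nm]][mine]
        cols[[sids[i]]] <- v
        meta[[sids[i]]] <- data.frame(sm[i, ], library = nm,
                                      stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(cbind, cols)
    samples <- do.call(rbind, meta)
    rownames(samples) <- NULL
  }
  structure(list(counts = counts,
                 gene_lengths = stats::setNames(ann$length, ann$gene_id),
                 samples = samples, accounting = accounting),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples; %d libraries\n",
              nrow(x$counts), ncol(x$counts), nrow(x$accounting)))
  invisible(x)
}
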