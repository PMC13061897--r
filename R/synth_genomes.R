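#' Generate toy strain genomes with shared and unique genes
#'
#' Builds one genome per strain in the design: random background sequence
#' with `n_genes` protein-coding-like genes embedded at spaced positions,
#' plus one rRNA-like sequence per strain. A chosen fraction of genes is
#' copied byte-identically into every strain's genome, so that reads from
#' those genes match all genomes equally well and exercise the
#' discard-ambiguous step of the deconvolution. Random k-mer collisions
#' between strains are negligible at the sequence lengths used (4^21
#' possible 21-mers), so with `shared_fraction = 0` no read from a gene
#' body can be ambiguous.
#'
#' @param design a [synth_design()].
#' @param genome_len genome length (bp) per strain.
#' @param n_genes genes per strain (shared + unique).
#' @param gene_len length of every gene (bp).
#' @param shared_fraction fraction in [0, 1) of genes shared verbatim
#'   across all strains; `round(shared_fraction * n_genes)` genes.
#' @param rrna_len length of the rRNA-like sequence (bp).
#' @param seed RNG seed; defaults to the design seed.
#' @return An object of class `synth_genomes`: `genomes` (named character,
#'   one sequence per strain), `rrna` (named character, one per strain),
#'   `annotation` (data frame: gene_id, base_id, strain, start, end,
#'   strand, length, shared; coordinates 1-based inclusive), `gene_seqs`
#'   (named by gene_id, as embedded in forward orientation of the gene).
#' @export
gen_genomes <- function(design, genome_len = 60000L, n_genes = 20L,
                        gene_len = 600L, shared_fraction = 0,
                        rrna_len = 1500L, seed = design$seed) {
  if (shared_fraction < 0 || shared_fraction >= 1)
    stopf("shared_fraction must be in [0, 1)")
  needed <- n_genes * gene_len + rrna_len
  if (genome_len < needed)
    stopf("impossible packing: %d genes x %d bp + %d bp rRNA = %d bp exceed genome_len %d",
          n_genes, gene_len, rrna_len, needed, genome_len)
  strains <- design$strains
  n_shared <- round(shared_fraction * n_genes)
  n_unique <- n_genes - n_shared
  with_seed(seed, {
    shared_seqs <- if (n_shared > 0)
      vapply(seq_len(n_shared), function(i) random_dna(gene_len), "") else character(0)
    names(shared_seqs) <- if (n_shared > 0) sprintf("s%02d", seq_len(n_shared)) else NULL
    genomes <- character(length(strains)); names(genomes) <- strains
    rrna <- character(length(strains)); names(rrna) <- strains
    ann <- list(); gene_seqs <- character(0)
    for (st in strains) {
      uniq_seqs <- if (n_unique > 0)
        vapply(seq_len(n_unique), function(i) random_dna(gene_len), "") else character(0)
      names(uniq_seqs) <- if (n_unique > 0) sprintf("u%02d", seq_len(n_unique)) else NULL
      rrna[[st]] <- random_dna(rrna_len)
      base_ids <- c(names(shared_seqs), names(uniq_seqs))
      seqs <- c(shared_seqs, uniq_seqs)
      lens <- c(rep(gene_len, n_genes), rrna_len)
      feats <- c(seqs, rrna = rrna[[st]])
      # random spacer gaps between features, spending the genome slack
      slack <- genome_len - sum(lens)
      gaps <- as.vector(stats::rmultinom(1, slack, rep(1, length(feats) + 1L)))
      ord <- sample(length(feats))           # random feature order
      feats <- feats[ord]; lens <- lens[ord]
      strands <- sample(c("+", "-"), length(feats), replace = TRUE)
      g <- random_dna(genome_len)
      pos <- gaps[1] + 1L
      starts <- integer(length(feats))
      for (i in seq_along(feats)) {
        s <- if (strands[i] == "+") feats[i] else revcomp(feats[i])
        substr(g, pos, pos + lens[i] - 1L) <- s
        starts[i] <- pos
        pos <- pos + lens[i] + gaps[i + 1L]
      }
      genomes[[st]] <- g
      idx <- names(feats) != "rrna"
      base <- names(feats)[idx]
      ann[[st]] <- data.frame(
        gene_id = sprintf("%s_%s", st, base), base_id = base, strain = st,
        start = starts[idx], end = starts[idx] + gene_len - 1L,
        strand = strands[idx], length = gene_len,
        shared = grepl("^s", base), stringsAsFactors = FALSE)
      gs <- feats[idx]; names(gs) <- sprintf("%s_%s", st, base)
      gene_seqs <- c(gene_seqs, gs)
    }
    annotation <- do.call(rbind, ann)
    rownames(annotation) <- NULL
    structure(list(genomes = genomes, rrna = rrna, annotation = annotation,
                   gene_seqs = gene_seqs,
                   params = list(genome_len = genome_len, n_genes = n_genes,
                                 gene_len = gene_len,
                                 shared_fraction = shared_fraction,
                                 rrna_len = rrna_len, seed = seed)),
              class = "synth_genomes")
  })
}

#' Write synthetic genomes to FASTA plus an annotation TSV
#'
#' One FASTA per strain (`<strain>.fasta`), one combined rRNA FASTA
#' (`rrna.fasta`) and the gene annotation as `annotation.tsv` with
#' 1-based inclusive coordinates.
#'
#' @param genomes a [gen_genomes()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of paths written.
#' @export
write_genomes <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (st in names(genomes$genomes)) {
    p <- file.path(dir, paste0(st, ".fasta"))
    x <- Biostrings::DNAStringSet(genomes$genomes[st])
    Biostrings::writeXStringSet(x, p)
    paths <- c(paths, p)
  }
  rp <- file.path(dir, "rrna.fasta")
  rr <- Biostrings::DNAStringSet(genomes$rrna)
  names(rr) <- paste0("rrna_", names(genomes$rrna))
  Biostrings::writeXStringSet(rr, rp)
  ap <- file.path(dir, "annotation.tsv")
  write_tsv(genomes$annotation, ap)
  invisible(c(paths, rp, ap))
}

#' Generate synthetic gene-to-KO and KO-to-pathway maps
#'
#' Emulates an eggNOG-style annotation: each gene maps to at most one
#' KEGG-Orthology-like identifier, and pathways are sets of KO ids. When
#' the KO universe can be partitioned into `n_pathways` disjoint blocks of
#' `genes_per_pathway` the pathways are disjoint; otherwise membership is
#' sampled and pathways may overlap.
#'
#' @param gene_ids character vector of gene identifiers (the annotation
#'   universe), or an integer giving how many `g<i>` ids to invent.
#' @param n_pathways number of pathways.
#' @param genes_per_pathway KO ids per pathway (>= 1).
#' @param ko_fraction fraction of genes that receive a KO id.
#' @param seed RNG seed.
#' @return list with data frames `gene2ko` (gene_id, ko) and `ko2path`
#'   (ko, pathway).
#' @export
gen_annotation <- function(gene_ids, n_pathways, genes_per_pathway,
                           ko_fraction = 1, seed = 1L) {
  if (genes_per_pathway < 1) stopf("genes_per_pathway must be >= 1")
  if (is.numeric(gene_ids) && length(gene_ids) == 1L)
    gene_ids <- sprintf("g%04d", seq_len(gene_ids))
  with_seed(seed, {
    n <- length(gene_ids)
    mapped <- sort(sample(n, round(ko_fraction * n)))
    kos <- sprintf("K%05d", seq_along(mapped))
    gene2ko <- data.frame(gene_id = gene_ids[mapped], ko = kos,
                          stringsAsFactors = FALSE)
    need <- n_pathways * genes_per_pathway
    if (need <= length(kos)) {
      picked <- matrix(sample(kos, need), nrow = genes_per_pathway)
    } else {
      picked <- vapply(seq_len(n_pathways), function(i)
        sample(kos, min(genes_per_pathway, length(kos))),
        character(min(genes_per_pathway, length(kos))))
      picked <- matrix(picked, ncol = n_pathways)
    }
    ko2path <- data.frame(
      ko = as.vector(picked),
      pathway = rep(sprintf("path%03d", seq_len(n_pathways)),
                    each = nrow(picked)),
      stringsAsFactors = FALSE)
    list(gene2ko = gene2ko, ko2path = ko2path)
  })
}
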