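# Hypergeometric upper tail P(X >= k) computed in log space via
# log-gamma (lchoose), summing the pmf from k to min(K, n). Robust for
# large N where direct factorials overflow.
hyper_upper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  if (length(i) == 0L || k > min(K, n)) return(0)
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Hypergeometric pathway over-representation analysis
#'
#' For a query gene set (e.g. upregulated genes, analysed separately from
#' the downregulated set), tests each pathway for over-representation
#' against the background universe of genes carrying a KO annotation (the
#' enrichKEGG convention; `universe = "annotated"` uses all genes in the
#' gene-to-KO table's gene universe). The p-value is the hypergeometric
#' upper tail P(X >= k) with N background genes, K of them in the
#' pathway, a query of size n and overlap k, computed in log space.
#' Pathways with fewer than `min_size` background genes are not tested.
#' BH adjustment runs across tested pathways. Duplicate query ids are
#' removed before testing.
#'
#' @param query character vector of gene ids.
#' @param gene2ko data frame gene_id, ko (one KO per gene at most).
#' @param ko2path data frame ko, pathway.
#' @param min_size minimum pathway gene-set size (default 10).
#' @param p_cut adjusted-p cutoff for the `significant` flag.
#' @param universe `"ko_mapped"` (genes with a KO; default) or
#'   `"annotated"` (every gene in `gene2ko$gene_id`, which coincides
#'   unless unmapped genes are listed with NA KO).
#' @return data frame of class `enrichment_result`: pathway, K, N, n, k,
#'   p, padj, significant, genes (semicolon-joined overlap), ordered by p.
#' @export
hypergeom_enrich <- function(query, gene2ko, ko2path, min_size = 10L,
                             p_cut = 0.05, universe = c("ko_mapped",
                                                        "annotated")) {
  universe <- match.arg(universe)
  query <- unique(query)
  mapped <- gene2ko[!is.na(gene2ko$ko), , drop = FALSE]
  bg <- if (universe == "ko_mapped") unique(mapped$gene_id)
        else unique(gene2ko$gene_id)
  q <- intersect(query, bg)
  if (length(q) == 0L) {
    warnf("query is empty after restricting to the background universe")
    out <- data.frame(pathway = character(), K = integer(), N = integer(),
                      n = integer(), k = integer(), p = numeric(),
                      padj = numeric(), significant = logical(),
                      genes = character(), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", class(out))
    return(out)
  }
  N <- length(bg); n <- length(q)
  path_genes <- lapply(split(ko2path$ko, ko2path$pathway), function(kos)
    unique(mapped$gene_id[mapped$ko %in% kos]))
  path_genes <- lapply(path_genes, intersect, bg)
  Ks <- lengths(path_genes)
  path_genes <- path_genes[Ks >= min_size]
  if (length(path_genes) == 0L)
    stopf("no pathway reaches min_size = %d in the background", min_size)
  rows <- lapply(names(path_genes), function(pw) {
    g <- path_genes[[pw]]
    ov <- intersect(q, g)
    k <- length(ov)
    data.frame(pathway = pw, K = length(g), N = N, n = n, k = k,
               p = hyper_upper_tail(k, length(g), N, n),
               genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$padj < p_cut
  out <- out[order(out$p), c("pathway", "K", "N", "n", "k", "p", "padj",
                             "significant", "genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Extract an up- or down-regulated query set from a DE table
#'
#' Up: `padj <= padj_max` and `log2FC > lfc_min`; down: `padj <= padj_max`
#' and `log2FC < -lfc_min` — the thresholds used to feed pathway
#' enrichment (adjusted p at most 0.05, absolute log2 fold change above 1).
#'
#' @param de a [differential_expression()] result (or any data frame with
#'   gene_id, log2FC, padj).
#' @param direction `"up"` or `"down"`.
#' @param padj_max adjusted-p threshold.
#' @param lfc_min absolute log2 fold-change threshold (strict inequality).
#' @return character vector of gene ids.
#' @export
de_to_query <- function(de, direction = c("up", "down"), padj_max = 0.05,
                        lfc_min = 1) {
  direction <- match.arg(direction)
  ok <- !is.na(de$padj) & de$padj <= padj_max &
    (if (direction == "up") de$log2FC > lfc_min else de$log2FC < -lfc_min)
  de$gene_id[ok]
}
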