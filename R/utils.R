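#' @keywords internal
#' @importFrom MASS negative.binomial
#' @importFrom stats p.adjust
"_PACKAGE"

# Evaluate expr with a local RNG state seeded at `seed`; the caller's
# .Random.seed is restored afterwards so generators never perturb the
# session RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed < 2^31 from a base seed and an index; deterministic
# and collision-free for the index ranges used here.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + index * 7919) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Write a data frame as TSV
#'
#' Plain `write.table` wrapper with the conventions used throughout the
#' package: tab separator, no quoting, no row names.
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

# Reverse complement for plain character vectors of A/C/G/T sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All k-mers of every sequence in `x` (equal lengths not required).
# Returns a list parallel to `x`; sequences shorter than k give character(0).
kmerize <- function(x, k) {
  lapply(x, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, seq_len(n - k + 1L), seq.int(k, n))
  })
}

# Fast path for a vector of equal-length sequences: matrix of k-mers with
# one row per sequence.
kmerize_equal <- function(x, k) {
  n <- unique(nchar(x))
  stopifnot(length(n) == 1L, n >= k)
  nk <- n - k + 1L
  starts <- seq_len(nk)
  m <- matrix("", nrow = length(x), ncol = nk)
  for (j in starts) m[, j] <- substr(x, j, j + k - 1L)
  m
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
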