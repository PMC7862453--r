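# Shared low-level helpers: seeded evaluation, random sequence generation,
# string/sequence utilities.  Sequences cross module boundaries as plain
# uppercase character scalars; Biostrings objects are used internally where
# they buy real functionality (IUPAC matching, reverse complement, FASTA).

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package operations
#' do not disturb the caller's random stream.  A `NULL` seed evaluates the
#' expression with the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Generate a random DNA sequence
#'
#' I.i.d. nucleotides at the requested GC content.
#'
#' @param n Length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @return Uppercase character scalar of length-`n` DNA.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a DNA string (IUPAC-aware)
#' @param x DNA character scalar.
#' @return Reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Substring with 1-based inclusive coordinates
#' @param x Character scalar.
#' @param start,end 1-based inclusive bounds.
#' @return The sub-sequence.
#' @export
subseq_chr <- function(x, start, end) substr(x, start, end)

# fast per-position string vector
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Hamming distance between equal-length strings (compiled)
hamming <- function(x, y) .hamming_cpp(x, y)

# rotate a circular sequence left by `by` positions (by = 0 returns input)
rotate_seq <- function(x, by) {
  n <- nchar(x)
  by <- by %% n
  if (by == 0) return(x)
  paste0(substr(x, by + 1, n), substr(x, 1, by))
}

IUPAC_LETTERS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

is_valid_iupac <- function(x) {
  !grepl(paste0("[^", paste(IUPAC_LETTERS, collapse = ""), "]"), x)
}

# standard error of the mean
sem <- function(x) if (length(x) < 2) 0 else sd(x) / sqrt(length(x))
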