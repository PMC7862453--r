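# Finishing of circular clone assemblies and contig merging.
#
# A valid assembly of a circular TAR/YAC/BAC molecule contains the vector
# sequence, possibly a duplicated terminal segment ("circular overlap"), and
# the targeting hooks.  Finishing removes the circular overlap, locates and
# removes the vector, re-orients the sequence to begin at the first base
# after the removed vector, and verifies the hooks.

#' Trim the circular overlap of a linearized circular assembly
#'
#' Removes the longest terminal suffix that matches the prefix with at most
#' `max_divergence` mismatches, once, from the end.  The overlap is required
#' to be shorter than half the sequence so whole-sequence self-identity is
#' never treated as an overlap.  Idempotent on clean sequences.
#'
#' @param sequence DNA character scalar.
#' @param min_overlap Minimum overlap length considered (default 100 bp).
#' @param max_divergence Maximum mismatch fraction in the overlap
#'   (default 0.01).
#' @param seed_k Exact seed length used to locate candidate overlaps.
#' @return List with `sequence` (trimmed) and `removed` (bp removed).
#' @export
trim_circular_overlap <- function(sequence, min_overlap = 100,
                                  max_divergence = 0.01, seed_k = NULL) {
  n <- nchar(sequence)
  max_ov <- (n - 1) %/% 2
  if (max_ov < min_overlap)
    return(list(sequence = sequence, removed = 0L))
  if (is.null(seed_k)) seed_k <- min(31L, min_overlap)
  seed <- substr(sequence, 1, seed_k)
  tail_start <- n - max_ov + 1L
  tail_seq <- substr(sequence, tail_start, n)
  hits <- BiocGenerics::start(
    Biostrings::matchPattern(seed, Biostrings::DNAString(tail_seq)))
  if (!length(hits)) return(list(sequence = sequence, removed = 0L))
  cand <- sort(n - (tail_start + hits - 1L) + 1L, decreasing = TRUE)
  cand <- cand[cand >= min_overlap]
  for (ov in cand) {
    mism <- hamming(substr(sequence, n - ov + 1L, n), substr(sequence, 1, ov))
    if (mism <= max_divergence * ov)
      return(list(sequence = substr(sequence, 1, n - ov), removed = as.integer(ov)))
  }
  list(sequence = sequence, removed = 0L)
}

# locate `vector_seq` in the circular sequence `s` (searching across the
# origin via doubling); exact match first, then a local-alignment fallback
# requiring >= min_identity over >= min_coverage of the vector length.
# Returns c(start, end) with end possibly > nchar(s) (wrapping), or NULL.
locate_vector <- function(s, vector_seq, min_identity = 0.95,
                          min_coverage = 0.90) {
  n <- nchar(s)
  vl <- nchar(vector_seq)
  if (vl > n) return(NULL)
  doubled <- paste0(s, substr(s, 1, min(n, vl) - 1L))
  hits <- BiocGenerics::start(
    Biostrings::matchPattern(vector_seq, Biostrings::DNAString(doubled)))
  hits <- hits[hits <= n]
  if (length(hits)) return(c(hits[1], hits[1] + vl - 1L))
  # alignment fallback for assemblies with residual consensus error
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(vector_seq), Biostrings::DNAString(doubled),
    type = "local", substitutionMatrix =
      Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                               baseOnly = TRUE),
    gapOpening = 5, gapExtension = 1)
  pr <- Biostrings::pattern(al)
  covered <- BiocGenerics::end(pr) - BiocGenerics::start(pr) + 1L
  if (covered < min_coverage * vl) return(NULL)
  if (Biostrings::pid(al) / 100 < min_identity) return(NULL)
  st <- BiocGenerics::start(Biostrings::subject(al))
  en <- BiocGenerics::end(Biostrings::subject(al))
  if (st > n) { st <- st - n; en <- en - n }
  c(st, en)
}

#' Finish a circular clone assembly
#'
#' Trims the circular overlap, locates the vector (exact match or a local
#' alignment at >= 95% identity over >= 90% of the vector length, on either
#' strand), removes it, re-orients the sequence to start at the first base
#' after the removed vector, and checks that each hook occurs exactly once in
#' the insert.
#'
#' @param assembly Linearized assembly (character scalar).
#' @param vector_seq Vector sequence.
#' @param hooks Named character vector of hook sequences (e.g.
#'   `c(hook5 = ..., hook3 = ...)`).
#' @param min_overlap,max_divergence Passed to [trim_circular_overlap()].
#' @param min_identity,min_coverage Vector-detection thresholds.
#' @return A `finished_clone`: list with `insert`, `vector_interval_removed`,
#'   `circular_overlap_removed`, `reoriented_offset`, `strand`,
#'   `hooks_found` (named logical), `valid`.
#' @export
finish_assembly <- function(assembly, vector_seq, hooks = character(0),
                            min_overlap = 100, max_divergence = 0.01,
                            min_identity = 0.95, min_coverage = 0.90) {
  tr <- trim_circular_overlap(assembly, min_overlap, max_divergence)
  s <- tr$sequence
  n <- nchar(s)
  strand <- "+"
  vi <- locate_vector(s, vector_seq, min_identity, min_coverage)
  if (is.null(vi)) {
    vi <- locate_vector(s, revcomp(vector_seq), min_identity, min_coverage)
    if (!is.null(vi)) {
      s <- revcomp(s)
      strand <- "-"
      vi <- c(n - vi[2] + 1L, n - vi[1] + 1L)
      if (vi[1] < 1) vi <- vi + n  # wrapped interval after strand flip
    }
  }
  if (is.null(vi)) stop("vector absent")
  vend <- ((vi[2] - 1L) %% n) + 1L
  vstart <- ((vi[1] - 1L) %% n) + 1L
  if (vi[2] <= n) {
    insert <- paste0(substr(s, vend + 1L, n), substr(s, 1, vstart - 1L))
  } else {
    insert <- substr(s, vend + 1L, vstart - 1L)
  }
  hooks_found <- vapply(hooks, function(h)
    length(Biostrings::matchPattern(h, Biostrings::DNAString(insert))) == 1L,
    logical(1))
  structure(list(insert = insert,
                 vector_interval_removed = c(vstart, vi[2]),
                 circular_overlap_removed = tr$removed,
                 reoriented_offset = vstart - 1L,
                 strand = strand,
                 hooks_found = hooks_found,
                 valid = all(hooks_found)),
            class = "finished_clone")
}

#' @export
print.finished_clone <- function(x, ...) {
  cat(sprintf("<finished_clone> insert %d bp; overlap removed %d bp; strand %s; hooks: %s\n",
              nchar(x$insert), x$circular_overlap_removed, x$strand,
              if (length(x$hooks_found))
                paste(names(x$hooks_found), x$hooks_found, sep = "=",
                      collapse = ", ") else "none checked"))
  invisible(x)
}

# best suffix(x)/prefix(y) overlap via exact k-mer seeding; returns
# list(overlap, mismatches) or NULL
best_suffix_prefix <- function(x, y, min_overlap, max_mismatch_rate, k = 31L) {
  nx <- nchar(x); ny <- nchar(y)
  lim <- min(nx, ny) - 1L  # a full-containment "overlap" is not a merge
  if (lim < min_overlap) return(NULL)
  k <- min(k, max(4L, as.integer(min_overlap)))
  cand <- integer(0)
  for (off in c(0L, k, 2L * k, 3L * k)) {
    if (off + k > ny) break
    seeds <- substr(y, off + 1L, off + k)
    hits <- BiocGenerics::start(
      Biostrings::matchPattern(seeds, Biostrings::DNAString(x)))
    cand <- c(cand, nx - hits + 1L + off)
  }
  cand <- sort(unique(cand[cand >= min_overlap & cand <= lim]),
               decreasing = TRUE)
  best <- NULL
  for (ov in cand) {
    mism <- hamming(substr(x, nx - ov + 1L, nx), substr(y, 1, ov))
    if (mism <= max_mismatch_rate * ov)
      return(list(overlap = as.integer(ov), mismatches = mism))
    if (is.null(best) || mism / ov < best$mismatches / best$overlap)
      best <- list(overlap = as.integer(ov), mismatches = mism)
  }
  if (!is.null(best)) attr(best, "sub_threshold") <- TRUE
  best
}

#' Merge two finished inserts on their terminal overlap
#'
#' Searches the maximal suffix/prefix overlap over both input orders and both
#' strands of the second insert, using exact 31-mer seeding extended to the
#' full overlap with mismatch counting.  The longest qualifying overlap wins;
#' among equals, the fewest mismatches.
#'
#' @param insert_a,insert_b Insert sequences.
#' @param min_overlap Minimum acceptable overlap (default 100 bp).
#' @param max_mismatch_rate Maximum mismatch fraction in the overlap.
#' @param ids Length-2 character vector of source ids.
#' @return A `contig_merge`: list with `contig`, `overlap_length`,
#'   `mismatches_in_overlap`, `order`, `strand`, `sources`;
#'   `nchar(contig) == nchar(a) + nchar(b) - overlap_length`.
#' @export
merge_inserts <- function(insert_a, insert_b, min_overlap = 100,
                          max_mismatch_rate = 0.01, ids = c("A", "B")) {
  combos <- list(
    list(x = insert_a, y = insert_b, order = "AB", strand = "+"),
    list(x = insert_b, y = insert_a, order = "BA", strand = "+"),
    list(x = insert_a, y = revcomp(insert_b), order = "AB", strand = "-"),
    list(x = revcomp(insert_b), y = insert_a, order = "BA", strand = "-")
  )
  best <- NULL; best_combo <- NULL
  best_sub <- NULL; best_sub_combo <- NULL
  for (cb in combos) {
    r <- best_suffix_prefix(cb$x, cb$y, min_overlap, max_mismatch_rate)
    if (is.null(r)) next
    if (isTRUE(attr(r, "sub_threshold"))) {
      if (is.null(best_sub) || r$overlap > best_sub$overlap) {
        best_sub <- r; best_sub_combo <- cb
      }
      next
    }
    if (is.null(best) || r$overlap > best$overlap ||
        (r$overlap == best$overlap && r$mismatches < best$mismatches)) {
      best <- r; best_combo <- cb
    }
  }
  if (is.null(best)) {
    if (!is.null(best_sub))
      stop(sprintf(paste0("no qualifying overlap >= %d bp at mismatch rate ",
                          "<= %.3g; best sub-threshold candidate: %d bp with ",
                          "%d mismatches (%s order, %s strand)"),
                   min_overlap, max_mismatch_rate, best_sub$overlap,
                   best_sub$mismatches, best_sub_combo$order,
                   best_sub_combo$strand))
    stop("no qualifying overlap >= ", min_overlap, " bp found")
  }
  x <- best_combo$x; y <- best_combo$y
  contig <- paste0(x, substr(y, best$overlap + 1L, nchar(y)))
  structure(list(contig = contig, overlap_length = best$overlap,
                 mismatches_in_overlap = best$mismatches,
                 order = best_combo$order, strand = best_combo$strand,
                 sources = ids),
            class = "contig_merge")
}

#' @export
print.contig_merge <- function(x, ...) {
  cat(sprintf("<contig_merge> %s+%s (%s order, %s strand): %d bp contig, %d bp overlap, %d mismatch(es)\n",
              x$sources[1], x$sources[2], x$order, x$strand, nchar(x$contig),
              x$overlap_length, x$mismatches_in_overlap))
  invisible(x)
}
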