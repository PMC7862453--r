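# Independent brute-force oracles used across the suite.  Each deliberately
# avoids the implementation's algorithmic shortcuts (dynamic programming,
# banding, k-mer seeding) so that agreement is informative.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# naive per-position IUPAC matcher, both strands, palindromes once
oracle_scan <- function(sequence, motif) {
  ch <- strsplit(sequence, "")[[1]]
  match_at <- function(motif_chars, p) {
    for (i in seq_along(motif_chars)) {
      b <- ch[p + i - 1]
      if (!(b %in% IUPAC_SETS[[motif_chars[i]]])) return(FALSE)
    }
    TRUE
  }
  k <- nchar(motif)
  n <- nchar(sequence)
  if (n < k) return(integer(0))
  fw <- strsplit(motif, "")[[1]]
  rc <- strsplit(norkit::revcomp(motif), "")[[1]]
  hits <- integer(0)
  for (p in seq_len(n - k + 1)) {
    if (match_at(fw, p) || match_at(rc, p)) hits <- c(hits, p)
  }
  hits
}

# enumerate every non-crossing structure with hairpin loops >= min_loop;
# returns a list of two-column pair matrices (including the empty structure)
oracle_enumerate_structures <- function(n, pairable, min_loop = 3) {
  # pairable: n x n logical matrix
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(list(matrix(0L, 0, 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- list()
    # i unpaired
    for (s in rec(i + 1, j)) out[[length(out) + 1L]] <- s
    # i paired with k
    for (k in seq(i + min_loop + 1, j)) {
      if (!pairable[i, k]) next
      inner <- rec(i + 1, k - 1)
      outer <- rec(k + 1, j)
      for (si in inner) for (so in outer)
        out[[length(out) + 1L]] <- rbind(matrix(c(i, k), 1, 2), si, so)
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

rna_pairable_matrix <- function(seq_rna) {
  ch <- strsplit(chartr("T", "U", toupper(seq_rna)), "")[[1]]
  n <- length(ch)
  ok <- function(x, y) {
    p <- paste0(x, y)
    p %in% c("GC", "CG", "AU", "UA", "GU", "UG")
  }
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) m[i, j] <- ok(ch[i], ch[j])
  m
}

oracle_score_structure <- function(pairs, seq_rna, model,
                                   weights = c(GC = 3, AU = 2, GU = 1),
                                   stack_bonus = 1) {
  if (nrow(pairs) == 0) return(0)
  if (model == "pairmax") return(nrow(pairs))
  ch <- strsplit(chartr("T", "U", toupper(seq_rna)), "")[[1]]
  w <- 0
  keyset <- paste(pairs[, 1], pairs[, 2])
  for (r in seq_len(nrow(pairs))) {
    p <- paste0(sort(c(ch[pairs[r, 1]], ch[pairs[r, 2]])), collapse = "")
    w <- w + switch(p, CG = weights[["GC"]], AU = weights[["AU"]],
                    GU = weights[["GU"]], 0)
    if (paste(pairs[r, 1] + 1, pairs[r, 2] - 1) %in% keyset)
      w <- w + stack_bonus
  }
  w
}

# best score over all enumerated structures, optionally with positions that
# must stay unpaired
oracle_best_fold <- function(seq_rna, model, min_loop = 3,
                             unpaired = integer(0)) {
  n <- nchar(seq_rna)
  pm <- rna_pairable_matrix(seq_rna)
  if (length(unpaired)) { pm[unpaired, ] <- FALSE; pm[, unpaired] <- FALSE }
  structs <- oracle_enumerate_structures(n, pm, min_loop)
  best <- 0
  for (s in structs) {
    sc <- oracle_score_structure(s, seq_rna, model)
    if (sc > best) best <- sc
  }
  best
}

# brute-force longest terminal suffix-prefix repeat (allowing mismatch rate)
oracle_terminal_overlap <- function(s, min_overlap, max_divergence) {
  n <- nchar(s)
  best <- 0L
  for (ov in seq_len((n - 1) %/% 2)) {
    if (ov < min_overlap) next
    a <- substr(s, n - ov + 1, n); b <- substr(s, 1, ov)
    mism <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (mism <= max_divergence * ov) best <- ov
  }
  best
}

# brute-force best suffix(x)/prefix(y) overlap
oracle_suffix_prefix <- function(x, y, min_overlap, max_rate) {
  nx <- nchar(x); ny <- nchar(y)
  best <- NULL
  for (ov in seq(min(nx, ny) - 1, 1)) {
    if (ov < min_overlap) break
    a <- substr(x, nx - ov + 1, nx); b <- substr(y, 1, ov)
    mism <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (mism <= max_rate * ov) { best <- list(overlap = ov, mism = mism); break }
  }
  best
}

# naive sharing classifier (independent of classify_sharing's set logic)
oracle_sharing <- function(variant_sets, groups) {
  keys <- unique(unlist(variant_sets))
  all_groups <- unique(unname(groups[names(variant_sets)]))
  res <- character(length(keys)); names(res) <- keys
  for (k in keys) {
    carriers <- character(0)
    for (u in names(variant_sets))
      if (k %in% variant_sets[[u]]) carriers <- c(carriers, u)
    gs <- unique(unname(groups[carriers]))
    res[k] <- if (length(carriers) == 1) "unique"
      else if (length(setdiff(all_groups, gs)) == 0) "universal"
      else "shared"
  }
  res
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

# reconstruct a mutated unit from the reference and its truth records
apply_truth_variants <- function(ref, variants) {
  if (!nrow(variants)) return(ref)
  v <- variants[order(-variants$pos), , drop = FALSE]
  s <- ref
  for (i in seq_len(nrow(v)))
    s <- norkit::apply_variant(s, as.list(v[i, ]))
  s
}
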