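# RNA secondary-structure impact scoring of allelic variants.
#
# Two exact built-in folding models are provided: base-pair maximization and
# a weighted-stack model (GC=3, AU=2, GU=1, +1 per stacked pair) that serves
# as a nearest-neighbour-flavoured stand-in.  Both are dynamic programs whose
# optima are verified against exhaustive structure enumeration in the test
# suite, which is what makes the downstream statistics (opening penalties,
# structural index D, randomization nulls) auditable at desk scale.  An
# external thermodynamic folding engine can be plugged in through the
# `backend` element of [fold_params()]: any function
# `function(sequence, params)` returning an `rna_structure`.

#' Folding parameters
#'
#' @param model `"pairmax"` or `"stacks"`.
#' @param min_loop Minimum hairpin loop length (nt, default 3).
#' @param windows Window lengths (nt) used when scoring variants,
#'   default `c(100, 350)`.
#' @param step Step (nt) for scanning windows, default 10.
#' @param weights Pair weights for the stacks model.
#' @param stack_bonus Bonus per stacked pair (stacks model).
#' @param backend Optional external folding function.
#' @return A `fold_params` list.
#' @export
fold_params <- function(model = c("pairmax", "stacks"), min_loop = 3L,
                        windows = c(100L, 350L), step = 10L,
                        weights = c(GC = 3, AU = 2, GU = 1), stack_bonus = 1,
                        backend = NULL) {
  model <- match.arg(model)
  stopifnot(min_loop >= 0, all(windows >= 2 * min_loop), step >= 1)
  structure(list(model = model, min_loop = as.integer(min_loop),
                 windows = as.integer(windows), step = as.integer(step),
                 weights = weights, stack_bonus = stack_bonus,
                 backend = backend),
            class = "fold_params")
}

as_rna <- function(sequence) chartr("Tt", "Uu", toupper(sequence))

#' Fold an RNA sequence
#'
#' Computes the optimal secondary structure under the selected model
#' (non-crossing pairs, hairpin loops >= `min_loop`).  DNA input is read as
#' RNA (T as U).  Sequences too short to pair fold to the all-unpaired
#' structure.
#'
#' @param sequence RNA or DNA character scalar.
#' @param params A [fold_params()].
#' @param unpaired Optional integer vector of 1-based positions forced
#'   unpaired (folding constraint).
#' @return An `rna_structure`: list with `length`, `partner` (0 = unpaired),
#'   `pairs` (two-column matrix, i < j), `score`, `model`.
#' @export
fold <- function(sequence, params = fold_params(), unpaired = NULL) {
  if (!is.null(params$backend) && is.null(unpaired))
    return(params$backend(sequence, params))
  s <- as_rna(sequence)
  n <- nchar(s)
  mask <- rep(FALSE, n)
  if (!is.null(unpaired)) {
    stopifnot(all(unpaired >= 1), all(unpaired <= n))
    mask[unpaired] <- TRUE
  }
  r <- .fold_cpp(s, ifelse(params$model == "pairmax", 0L, 1L),
                 params$min_loop, mask,
                 params$weights[["GC"]], params$weights[["AU"]],
                 params$weights[["GU"]], params$stack_bonus)
  partner <- r$partner
  i <- which(partner > seq_len(n))
  pairs <- cbind(i = i, j = partner[i])
  structure(list(length = n, partner = partner, pairs = pairs,
                 score = r$score, model = params$model),
            class = "rna_structure")
}

#' Render a structure in dot-bracket notation
#' @param structure An `rna_structure`.
#' @return Character scalar of `.`, `(`, `)`.
#' @export
dot_bracket <- function(structure) {
  n <- structure$length
  out <- rep(".", n)
  if (nrow(structure$pairs)) {
    out[structure$pairs[, 1]] <- "("
    out[structure$pairs[, 2]] <- ")"
  }
  paste(out, collapse = "")
}

#' Parse dot-bracket notation into an `rna_structure`
#' @param x Dot-bracket character scalar.
#' @return An `rna_structure` (score `NA`).
#' @export
parse_dot_bracket <- function(x) {
  ch <- str_chars(x)
  if (any(!ch %in% c(".", "(", ")"))) stop("invalid dot-bracket characters")
  n <- length(ch)
  partner <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced brackets at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced brackets: ", length(stack), " unclosed")
  i <- which(partner > seq_len(n))
  structure(list(length = n, partner = partner,
                 pairs = cbind(i = i, j = partner[i]), score = NA_real_,
                 model = "parsed"),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("<rna_structure> %d nt, %d pair(s), score %.3g (%s)\n",
              x$length, nrow(x$pairs), x$score, x$model))
  if (x$length <= 120) cat(dot_bracket(x), "\n")
  invisible(x)
}

#' Opening penalty of an interval
#'
#' The score penalty for forcing an interval unpaired relative to the
#' unconstrained optimum ("target structure opening").  Non-negative; zero
#' exactly when the interval is already unpaired in some optimum.
#'
#' @param sequence RNA/DNA character scalar (one folding window).
#' @param interval Integer `c(start, end)` within the sequence.
#' @param params A [fold_params()].
#' @return List with `interval`, `delta_g_open`, `score_free`,
#'   `score_constrained`.
#' @export
opening_penalty <- function(sequence, interval, params = fold_params()) {
  n <- nchar(sequence)
  if (interval[1] < 1 || interval[2] > n || interval[2] < interval[1])
    stop("interval outside sequence")
  if (interval[2] - interval[1] + 1 > min(params$windows))
    stop("interval longer than the folding window")
  free <- fold(sequence, params)
  constrained <- fold(sequence, params, unpaired = interval[1]:interval[2])
  list(interval = as.integer(interval),
       delta_g_open = free$score - constrained$score,
       score_free = free$score, score_constrained = constrained$score)
}

pair_set <- function(pairs) {
  if (!nrow(pairs)) return(character(0))
  paste(pairs[, 1], pairs[, 2], sep = "-")
}

#' Structural index D between two structures
#'
#' Euclidean distance between the binary base-pair indicator vectors of the
#' two structures in a common coordinate frame:
#' `D = sqrt(|pairs(s1) XOR pairs(s2)|)`.  When the structures come from
#' alleles of different length, `map` carries s2 positions into the s1 frame
#' (NA = position absent from the frame); a pair with an unmapped endpoint
#' cannot match any s1 pair and contributes to the symmetric difference.
#'
#' @param s1,s2 `rna_structure` objects.
#' @param map Optional integer vector, `length(map) == s2$length`, mapping s2
#'   positions to s1 coordinates.
#' @return Non-negative numeric `D` (0 for identical structures).
#' @export
structural_index <- function(s1, s2, map = NULL) {
  if (is.null(map)) {
    if (s1$length != s2$length)
      stop("structures of different length need a coordinate map")
    p2 <- pair_set(s2$pairs)
  } else {
    stopifnot(length(map) == s2$length)
    p2 <- character(0)
    if (nrow(s2$pairs)) {
      i2 <- map[s2$pairs[, 1]]; j2 <- map[s2$pairs[, 2]]
      ok <- !is.na(i2) & !is.na(j2)
      p2 <- if (any(ok)) paste(i2[ok], j2[ok], sep = "-") else character(0)
      if (any(!ok)) p2 <- c(p2, paste0("unmapped", which(!ok)))
    }
  }
  p1 <- pair_set(s1$pairs)
  sqrt(length(union(setdiff(p1, p2), setdiff(p2, p1))))
}

#' Coordinate map between two alleles
#'
#' Aligns the alleles and maps each position of `alt_seq` to its reference
#' coordinate (NA at inserted positions).
#'
#' @param ref_seq,alt_seq Allele sequences.
#' @param ... Passed to [align_units()].
#' @return Integer vector of length `nchar(alt_seq)`.
#' @export
allele_coordinate_map <- function(ref_seq, alt_seq, ...) {
  pair <- align_units(ref_seq, alt_seq, ...)
  ops <- pair$ops
  refpos <- cumsum(ops %in% c(0L, 1L, 3L))
  map <- rep(NA_integer_, nchar(alt_seq))
  bcols <- ops %in% c(0L, 1L, 2L)
  bpos <- cumsum(bcols)
  keep <- which(ops %in% c(0L, 1L))
  map[bpos[keep]] <- refpos[keep]
  map
}

#' Apply one variant to a sequence
#' @param sequence Character scalar.
#' @param variant List/row with `pos`, `type`, `ref`, `alt`.
#' @return Mutated sequence.
#' @export
apply_variant <- function(sequence, variant) {
  pos <- variant$pos
  switch(variant$type,
    SNV = { substr(sequence, pos, pos) <- variant$alt; sequence },
    DEL = paste0(substr(sequence, 1, pos - 1),
                 substr(sequence, pos + nchar(variant$ref), nchar(sequence))),
    INS = paste0(substr(sequence, 1, pos), variant$alt,
                 substr(sequence, pos + 1, nchar(sequence))),
    stop("unknown variant type ", variant$type))
}

#' Shuffle a sequence preserving composition
#'
#' Mononucleotide shuffle by default; `"dinucleotide"` preserves
#' dinucleotide counts (Altschul-Erickson style edge shuffle with a
#' connectivity check).
#'
#' @param sequence Character scalar.
#' @param method `"mono"` or `"dinucleotide"`.
#' @return Shuffled sequence.
#' @export
shuffle_seq <- function(sequence, method = c("mono", "dinucleotide")) {
  method <- match.arg(method)
  ch <- str_chars(sequence)
  n <- length(ch)
  if (n < 2) return(sequence)
  if (method == "mono") return(paste(sample(ch), collapse = ""))
  # dinucleotide shuffle: random Eulerian path over the letter graph
  for (try in 1:1000) {
    edges <- split(ch[-1], ch[-n])          # from-letter -> multiset of next
    edges <- lapply(edges, sample)
    walk <- character(n); walk[1] <- ch[1]
    ptr <- lapply(edges, function(e) 1L)
    ok <- TRUE
    cur <- ch[1]
    for (i in 2:n) {
      k <- ptr[[cur]]
      if (is.null(k) || k > length(edges[[cur]])) { ok <- FALSE; break }
      nxt <- edges[[cur]][k]
      ptr[[cur]] <- k + 1L
      walk[i] <- nxt
      cur <- nxt
    }
    if (ok) return(paste(walk, collapse = ""))
  }
  stop("dinucleotide shuffle failed to find an Eulerian walk")
}

#' Randomization null for a variant's structural statistic
#'
#' Shuffles the window sequence (composition-preserving), re-applies the
#' variant at the same offset, and recomputes the statistic, `n` times.  The
#' empirical P-value is `(r + 1) / (n + 1)` with `r` the number of null
#' values >= the observed one; the z-score is
#' `(obs - mean(null)) / sd(null)` (NA when the null is degenerate).
#'
#' @param sequence Window sequence (reference allele).
#' @param variant List/row with `pos`, `type`, `ref`, `alt` in window
#'   coordinates.
#' @param params A [fold_params()].
#' @param n Number of randomizations (>= 20; default 100).
#' @param seed Optional integer seed.
#' @param statistic `"D"` (structural index) or `"dG_open"` (absolute change
#'   in opening penalty of the variant footprint).
#' @param shuffle `"mono"` or `"dinucleotide"`.
#' @return List with `observed`, `null` (length n), `empirical_p`, `z`.
#' @export
randomization_null <- function(sequence, variant, params = fold_params(),
                               n = 100L, seed = NULL,
                               statistic = c("D", "dG_open"),
                               shuffle = c("mono", "dinucleotide")) {
  statistic <- match.arg(statistic)
  shuffle <- match.arg(shuffle)
  if (n < 20) stop("n must be >= 20")
  with_seed(seed, {
    stat_fun <- function(ref_win, v) {
      alt_win <- apply_variant(ref_win, v)
      if (statistic == "D") {
        s_ref <- fold(ref_win, params)
        s_alt <- fold(alt_win, params)
        map <- variant_coordinate_map(nchar(ref_win), nchar(alt_win), v)
        structural_index(s_ref, s_alt, map = map)
      } else {
        iv_ref <- variant_footprint(v)
        iv_alt <- variant_footprint_alt(v)
        p_ref <- opening_penalty(ref_win, iv_ref, params)$delta_g_open
        p_alt <- opening_penalty(alt_win, iv_alt, params)$delta_g_open
        abs(p_alt - p_ref)
      }
    }
    observed <- stat_fun(sequence, variant)
    # exchangeable null: the re-applied SNV must remain a substitution; if
    # the shuffled base at the offset already equals the alternate, the
    # alternate is redrawn among the other bases
    null_rep <- function() {
      shuf <- shuffle_seq(sequence, shuffle)
      v <- variant
      if (v$type == "SNV") {
        base <- substr(shuf, v$pos, v$pos)
        if (base == v$alt) {
          alphabet <- if (grepl("U", sequence, fixed = TRUE) ||
                          !grepl("T", sequence, fixed = TRUE))
            c("A", "C", "G", "U") else c("A", "C", "G", "T")
          v$alt <- sample(setdiff(alphabet, base), 1)
        }
      }
      stat_fun(shuf, v)
    }
    null <- vapply(seq_len(n), function(i) null_rep(), numeric(1))
    r <- sum(null >= observed)
    z <- if (sd(null) > 0) (observed - mean(null)) / sd(null) else NA_real_
    list(observed = observed, null = null,
         empirical_p = (r + 1) / (n + 1), z = z)
  })
}

# direct coordinate map alt -> ref for a single known variant (no alignment
# needed: positions before the event map to themselves, positions after shift
# by the indel length; inserted bases are unmapped)
variant_coordinate_map <- function(n_ref, n_alt, variant) {
  map <- seq_len(n_alt)
  if (variant$type == "SNV") return(map)
  if (variant$type == "INS") {
    l <- nchar(variant$alt)
    map[variant$pos + seq_len(l)] <- NA_integer_
    after <- (variant$pos + l + 1):n_alt
    if (variant$pos + l < n_alt) map[after] <- after - l
    return(map[seq_len(n_alt)])
  }
  l <- nchar(variant$ref)  # DEL
  if (variant$pos <= n_alt)
    map[variant$pos:n_alt] <- (variant$pos:n_alt) + l
  map
}

variant_footprint <- function(variant) {
  switch(variant$type,
         SNV = c(variant$pos, variant$pos),
         DEL = c(variant$pos, variant$pos + nchar(variant$ref) - 1L),
         INS = c(max(1L, variant$pos), variant$pos + 1L))
}

variant_footprint_alt <- function(variant) {
  switch(variant$type,
         SNV = c(variant$pos, variant$pos),
         DEL = c(max(1L, variant$pos - 1L), variant$pos),
         INS = c(variant$pos + 1L, variant$pos + nchar(variant$alt)))
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Exact two-sided P by full enumeration of group labelings when
#' `n_x + n_y <= exact_max`; otherwise the normal approximation with tie
#' correction.  Ties contribute 1/2 to U.  Completely tied samples give
#' p = 1.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_max Enumeration threshold (default 12).
#' @return List with `U` (for sample x), `p`, `method`.
#' @export
mww_test <- function(x, y, exact_max = 12L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  u_stat <- function(xs, ys) {
    sum(vapply(xs, function(v) sum(v > ys) + 0.5 * sum(v == ys), numeric(1)))
  }
  U <- u_stat(x, y)
  mu <- nx * ny / 2
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1)
    return(list(U = U, p = 1, method = "degenerate"))
  if (nx + ny <= exact_max) {
    picks <- combn(nx + ny, nx)
    us <- apply(picks, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p = p, method = "exact"))
  }
  n <- nx + ny
  ties <- table(pooled)
  sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu) / sqrt(sig2)
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Score a variant as a potential riboSNitch
#'
#' Folds windows centred on the variant for both alleles at each window
#' length, computes the structural index D and the change in opening penalty,
#' estimates an empirical P and z-score from composition-preserving
#' randomizations, and compares the per-offset opening-penalty profiles of
#' the two alleles with the MWW test.  The riboSNitch flag is raised when the
#' empirical P is <= `alpha` in at least one window length (per-variant
#' calls; no multiple-testing correction).
#'
#' @param ref_allele,alt_allele Allele sequences (pre-rRNA or rRNA region).
#' @param params A [fold_params()].
#' @param alpha Significance threshold (default 0.05).
#' @param n_rand Randomizations per window (default 100).
#' @param seed Optional integer seed.
#' @param statistic Statistic whose randomization P drives the flag:
#'   `"dG_open"` (default; change in the opening penalty of the variant
#'   footprint, robust to the degeneracy of optimal structures) or `"D"`
#'   (structural index).
#' @return An `impact_result`: list with `variant`, `windows` (per-window
#'   data frame: window, D, delta_delta_g_open, empirical_p, z, mww_u,
#'   mww_p), `ribosnitch`.
#' @export
call_ribosnitch <- function(ref_allele, alt_allele, params = fold_params(),
                            alpha = 0.05, n_rand = 100L, seed = NULL,
                            statistic = c("dG_open", "D")) {
  statistic <- match.arg(statistic)
  if (identical(toupper(ref_allele), toupper(alt_allele))) {
    return(structure(list(variant = NULL,
                          windows = data.frame(window = params$windows,
                                               D = 0, delta_delta_g_open = 0,
                                               empirical_p = 1, z = NA_real_,
                                               mww_u = NA_real_, mww_p = 1),
                          ribosnitch = FALSE),
                     class = "impact_result"))
  }
  pair <- align_units(ref_allele, alt_allele)
  vars <- call_variants(pair)
  v <- as.list(vars[1, ])
  rows <- list()
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      length(params$windows)))
  for (wi in seq_along(params$windows)) {
    w <- params$windows[wi]
    ctr <- v$pos
    ws <- max(1L, min(ctr - w %/% 2L, nchar(ref_allele) - w + 1L))
    we <- min(nchar(ref_allele), ws + w - 1L)
    ref_win <- substr(ref_allele, ws, we)
    v_win <- v
    v_win$pos <- v$pos - ws + 1L
    rn <- randomization_null(ref_win, v_win, params, n = n_rand,
                             seed = seeds[wi], statistic = statistic)
    iv_ref <- variant_footprint(v_win)
    iv_alt <- variant_footprint_alt(v_win)
    alt_win <- apply_variant(ref_win, v_win)
    s_ref <- fold(ref_win, params)
    s_alt <- fold(alt_win, params)
    D_obs <- structural_index(s_ref, s_alt,
                              map = variant_coordinate_map(nchar(ref_win),
                                                           nchar(alt_win),
                                                           v_win))
    ddg <- opening_penalty(alt_win, iv_alt, params)$delta_g_open -
      opening_penalty(ref_win, iv_ref, params)$delta_g_open
    prof <- allele_opening_profiles(ref_win, v_win, params)
    mww <- if (length(prof$ref) && length(prof$alt))
      mww_test(prof$ref, prof$alt) else list(U = NA_real_, p = NA_real_)
    rows[[wi]] <- data.frame(window = w, D = D_obs,
                             delta_delta_g_open = ddg,
                             empirical_p = rn$empirical_p, z = rn$z,
                             mww_u = mww$U, mww_p = mww$p)
  }
  windows <- do.call(rbind, rows)
  structure(list(variant = v, windows = windows,
                 ribosnitch = any(windows$empirical_p <= alpha)),
            class = "impact_result")
}

# opening penalties of the variant footprint measured in sub-windows scanned
# across the window at the configured step, for each allele
allele_opening_profiles <- function(ref_win, v_win, params) {
  alt_win <- apply_variant(ref_win, v_win)
  sub <- max(2 * params$min_loop + 2L, min(50L, nchar(ref_win)))
  scan <- function(s, center) {
    n <- nchar(s)
    starts <- seq(max(1L, center - sub + 1L), min(center, n - sub + 1L),
                  by = params$step)
    vapply(starts, function(st) {
      iv <- c(center, center)
      win <- substr(s, st, st + sub - 1L)
      opening_penalty(win, c(center - st + 1L, center - st + 1L),
                      params)$delta_g_open
    }, numeric(1))
  }
  list(ref = scan(ref_win, v_win$pos),
       alt = scan(alt_win, min(v_win$pos, nchar(alt_win))))
}

#' @export
print.impact_result <- function(x, ...) {
  cat(sprintf("<impact_result> riboSNitch: %s\n", x$ribosnitch))
  print(x$windows, row.names = FALSE)
  invisible(x)
}
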