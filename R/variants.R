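# Pairwise alignment of rDNA units, variant calling onto the reference-unit
# coordinate system, divergence, sharing and density statistics, and feature
# overlap mapping.
#
# Variant counting convention: one contiguous indel event of any length is
# one variant (so a 20-nucleotide indel is a single record); mismatches are
# counted individually.  These are descriptive counts; no multiple-testing
# correction applies anywhere in this module.

#' Banded global alignment of two rDNA units
#'
#' Needleman-Wunsch with affine gaps inside a diagonal band.  The band is
#' doubled until the optimum is stable (i.e. the score no longer changes),
#' up to `max_band`; highly divergent inputs that never stabilise are
#' rejected as non-homologous.
#'
#' @param a Reference unit sequence (first sequence = reference).
#' @param b Second unit sequence.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.  Defaults
#'   (+1/-2/-5/-1) suit <1% divergent ~43 kb units; counts depend on the
#'   aligner, so these are explicit arguments.
#' @param band Initial band half-width (default 200).
#' @param max_band Bail-out band (default 5000).
#' @return An `aligned_pair`: list with `a`, `b`, `ops` (integer codes per
#'   alignment column: 0 match, 1 mismatch, 2 insertion, 3 deletion),
#'   `score`, `band_used`, `scoring`.
#' @export
align_units <- function(a, b, match = 1, mismatch = -2, gap_open = -5,
                        gap_extend = -1, band = 200, max_band = 5000) {
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  n <- nchar(a); m <- nchar(b)
  band <- max(band, abs(n - m) + 10L)
  if (band > max_band)
    stop("length difference needs band > ", max_band,
         "; sequences are probably not homologous units")
  full_band <- n + m  # unbanded
  repeat {
    bw <- min(band, full_band)
    r <- .align_banded_cpp(a, b, match, mismatch, gap_open, gap_extend, bw)
    if (bw >= full_band) break
    r2 <- .align_banded_cpp(a, b, match, mismatch, gap_open, gap_extend,
                            min(2L * bw, full_band))
    if (r2$score == r$score) break
    band <- 2L * band
    if (band > max_band)
      stop("no stable optimum within band <= ", max_band,
           "; sequences are probably not homologous units")
  }
  stopifnot(sum(r$ops %in% c(0L, 1L, 3L)) == n,
            sum(r$ops %in% c(0L, 1L, 2L)) == m)
  structure(list(a = a, b = b, ops = r$ops, score = r$score,
                 band_used = as.integer(min(band, full_band)),
                 scoring = c(match = match, mismatch = mismatch,
                             gap_open = gap_open, gap_extend = gap_extend)),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("<aligned_pair> %d x %d bp, score %d, band %d; %d mismatch, %d ins, %d del column(s)\n",
              nchar(x$a), nchar(x$b), x$score, x$band_used,
              sum(x$ops == 1L), sum(x$ops == 2L), sum(x$ops == 3L)))
  invisible(x)
}

#' Call variants from an aligned pair onto the reference unit
#'
#' One record per mismatch and one per contiguous gap run; indels are
#' left-aligned against the reference.  Region labels come from `annotation`
#' (reference-unit coordinates); positions outside any annotated region get
#' `"unannotated"`, never dropped.
#'
#' @param pair An `aligned_pair` whose first sequence is the reference unit.
#' @param annotation Optional data frame `region`, `start`, `end`.
#' @return Data frame with `pos`, `type`, `ref`, `alt`, `region`.
#' @export
call_variants <- function(pair, annotation = NULL) {
  stopifnot(inherits(pair, "aligned_pair"))
  ops <- pair$ops
  refpos <- cumsum(ops %in% c(0L, 1L, 3L))
  altpos <- cumsum(ops %in% c(0L, 1L, 2L))
  rows <- list()
  # SNVs
  mis <- which(ops == 1L)
  for (i in mis) {
    rows[[length(rows) + 1L]] <- list(
      pos = refpos[i], type = "SNV",
      ref = substr(pair$a, refpos[i], refpos[i]),
      alt = substr(pair$b, altpos[i], altpos[i]))
  }
  # contiguous indel runs
  r <- rle(ops)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    v <- r$values[j]
    if (v == 2L) {  # insertion relative to reference
      anchor <- if (starts[j] == 1L) 0L else refpos[starts[j] - 1L]
      alt <- substr(pair$b, altpos[starts[j]], altpos[ends[j]])
      nv <- normalize_variant(pair$a, anchor, "INS", "", alt)
      rows[[length(rows) + 1L]] <- list(pos = nv$pos, type = "INS", ref = "",
                                        alt = nv$alt)
    } else if (v == 3L) {  # deletion from reference
      p <- refpos[starts[j]]
      ref <- substr(pair$a, refpos[starts[j]], refpos[ends[j]])
      nv <- normalize_variant(pair$a, p, "DEL", ref, "")
      rows[[length(rows) + 1L]] <- list(pos = nv$pos, type = "DEL",
                                        ref = nv$ref, alt = "")
    }
  }
  if (!length(rows))
    return(data.frame(pos = integer(0), type = character(0),
                      ref = character(0), alt = character(0),
                      region = character(0), stringsAsFactors = FALSE))
  out <- data.frame(pos = vapply(rows, `[[`, 0, "pos"),
                    type = vapply(rows, `[[`, "", "type"),
                    ref = vapply(rows, `[[`, "", "ref"),
                    alt = vapply(rows, `[[`, "", "alt"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos, out$type), , drop = FALSE]
  out$region <- assign_regions(out$pos, annotation)
  rownames(out) <- NULL
  out
}

assign_regions <- function(pos, annotation) {
  if (is.null(annotation) || !length(pos)) return(rep("unannotated", length(pos)))
  reg <- rep("unannotated", length(pos))
  for (i in seq_len(nrow(annotation))) {
    in_reg <- pos >= annotation$start[i] & pos <= annotation$end[i]
    reg[in_reg & reg == "unannotated"] <- annotation$region[i]
  }
  reg
}

#' Variant keys on the reference coordinate system
#' @param variants Data frame with `type`, `pos`, `ref`, `alt`.
#' @return Character vector of `type:pos:ref>alt` keys.
#' @export
variant_key <- function(variants) {
  if (!nrow(variants)) return(character(0))
  paste0(variants$type, ":", variants$pos, ":", variants$ref, ">", variants$alt)
}

#' Pairwise divergence among rDNA units
#'
#' Aligns every unordered pair of units, counts variants per pair, and
#' summarises mean and standard error of the mean within group labels
#' (within-group pairs per group, between-group pairs pooled, plus "all").
#'
#' @param units Named character vector of unit sequences (>= 2).
#' @param groups Optional named vector mapping unit name -> group label
#'   (e.g. chromosome or individual); default: one group.
#' @param ... Passed to [align_units()].
#' @return A `divergence_summary`: list with `pairs` (per-pair counts) and
#'   `summary` (per-label mean, se, n_pairs).
#' @export
pairwise_divergence <- function(units, groups = NULL, ...) {
  if (length(units) < 2) {
    warning("need >= 2 units for pairwise divergence")
    return(structure(list(pairs = data.frame(), summary = data.frame()),
                     class = "divergence_summary"))
  }
  if (is.null(names(units))) names(units) <- paste0("unit", seq_along(units))
  if (is.null(groups))
    groups <- setNames(rep("all_units", length(units)), names(units))
  idx <- combn(length(units), 2)
  pairs <- lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    n_var <- nrow(call_variants(align_units(units[[i]], units[[j]], ...)))
    ga <- groups[[names(units)[i]]]; gb <- groups[[names(units)[j]]]
    data.frame(unit_a = names(units)[i], unit_b = names(units)[j],
               count = n_var,
               label = if (ga == gb) paste0("within:", ga) else "between",
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  labels <- unique(c(pairs$label, "all"))
  summary <- do.call(rbind, lapply(labels, function(l) {
    x <- if (l == "all") pairs$count else pairs$count[pairs$label == l]
    data.frame(label = l, n_pairs = length(x), mean = mean(x), se = sem(x),
               stringsAsFactors = FALSE)
  }))
  structure(list(pairs = pairs, summary = summary),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat("<divergence_summary>\n")
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Classify variant sharing across units and chromosome groups
#'
#' `unique`: carried by a single unit.  `universal`: carried in every
#' chromosome group (and more than one unit).  `shared`: more than one unit
#' but not all groups.  The three classes partition the keys.
#'
#' @param variant_sets Named list: unit id -> character vector of variant keys
#'   (all on one reference coordinate system).
#' @param groups Named vector: unit id -> chromosome group.
#' @return Data frame with `key`, `n_units`, `n_groups`, `class`, `units`.
#' @export
classify_sharing <- function(variant_sets, groups) {
  if (!all(names(variant_sets) %in% names(groups)))
    stop("every unit in variant_sets needs a group")
  all_groups <- unique(groups[names(variant_sets)])
  keys <- unique(unlist(variant_sets, use.names = FALSE))
  if (!length(keys))
    return(data.frame(key = character(0), n_units = integer(0),
                      n_groups = integer(0), class = character(0),
                      units = character(0), stringsAsFactors = FALSE))
  rows <- lapply(keys, function(k) {
    carriers <- names(variant_sets)[vapply(variant_sets, function(s) k %in% s,
                                           logical(1))]
    gs <- unique(groups[carriers])
    cls <- if (length(carriers) == 1) "unique"
           else if (setequal(gs, all_groups)) "universal"
           else "shared"
    data.frame(key = k, n_units = length(carriers), n_groups = length(gs),
               class = cls, units = paste(carriers, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-region variant density
#'
#' @param variants Data frame with a `region` column (from [call_variants()]).
#' @param annotation Data frame `region`, `start`, `end` covering the
#'   reference unit.
#' @return List with `table` (region, length_bp, count, per_kb) and
#'   `igs_to_transcribed` (IGS density over pooled transcribed-region
#'   density).
#' @export
region_density <- function(variants, annotation) {
  len <- tapply(annotation$end - annotation$start + 1, annotation$region, sum)
  zero <- names(len)[len <= 0]
  if (length(zero)) {
    warning("excluding zero-length region(s): ", paste(zero, collapse = ", "))
    len <- len[len > 0]
  }
  regions <- intersect(NOR_REGIONS, names(len))
  if (!length(regions)) regions <- names(len)
  tab <- data.frame(region = regions,
                    length_bp = as.integer(len[regions]),
                    count = vapply(regions, function(r)
                      sum(variants$region == r), integer(1)),
                    stringsAsFactors = FALSE)
  tab$per_kb <- tab$count / (tab$length_bp / 1000)
  tx <- setdiff(regions, "IGS")
  ratio <- NA_real_
  if ("IGS" %in% regions && length(tx)) {
    igs_d <- tab$count[tab$region == "IGS"] / (tab$length_bp[tab$region == "IGS"] / 1000)
    tx_d <- sum(tab$count[tab$region %in% tx]) /
      (sum(tab$length_bp[tab$region %in% tx]) / 1000)
    ratio <- igs_d / tx_d
  }
  rownames(tab) <- NULL
  list(table = tab, igs_to_transcribed = ratio)
}

#' Map variants to annotated feature sites
#'
#' Reports, for each variant, the features it overlaps or lies within
#' `proximity` bp of, with a signed distance (negative upstream of the
#' feature start, positive downstream of its end, 0 inside).
#'
#' @param variants Data frame with `pos` (reference-unit coordinates).
#' @param features Data frame with `name`, `start`, `end`.
#' @param proximity Proximity threshold in bp (default 50).
#' @return Data frame with `key`, `pos`, `feature`, `distance`.
#' @export
map_to_features <- function(variants, features, proximity = 50) {
  for (i in seq_len(nrow(features))) {
    if (is.na(features$start[i]) || is.na(features$end[i]) ||
        features$end[i] < features$start[i])
      stop("malformed feature interval at line ", i)
  }
  keys <- variant_key(variants)
  if (!nrow(variants) || !nrow(features))
    return(data.frame(key = character(0), pos = integer(0),
                      feature = character(0), distance = integer(0),
                      stringsAsFactors = FALSE))
  q <- IRanges::IRanges(start = variants$pos, width = 1L)
  s <- IRanges::IRanges(start = features$start - proximity,
                        end = features$end + proximity)
  ov <- IRanges::findOverlaps(q, s)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  dist <- integer(length(qi))
  for (k in seq_along(qi)) {
    p <- variants$pos[qi[k]]
    fs <- features$start[si[k]]; fe <- features$end[si[k]]
    dist[k] <- if (p < fs) p - fs else if (p > fe) p - fe else 0L
  }
  out <- data.frame(key = keys[qi], pos = variants$pos[qi],
                    feature = features$name[si], distance = dist,
                    stringsAsFactors = FALSE)
  out[order(out$pos, out$feature), , drop = FALSE]
}
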