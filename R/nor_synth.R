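# Synthetic nucleolar organizer regions with known ground truth.
#
# A NOR is emitted as PJ flank + n tandem rDNA units + DJ flank.  Each unit
# derives from a single reference unit template by per-region Poisson
# mutation, so every downstream stage (enzyme selection, cloning, finishing,
# variant calling, density/divergence statistics) can be checked against
# stored truth.  Background sequence is i.i.d. at the requested GC content:
# downstream operations depend only on motif placement and edit structure,
# not on realistic k-mer composition.

# canonical region order within one rDNA unit
NOR_REGIONS <- c("5'ETS", "18S", "ITS1", "5.8S", "ITS2", "28S", "3'ETS", "IGS")

# full-scale region lengths (bp): ~13.4 kb transcribed region + ~29.6 kb IGS
# for a 43 kb unit, following the standard human 47S rDNA unit layout.
NOR_REGION_LENGTHS <- c(
  "5'ETS" = 3657L, "18S" = 1869L, "ITS1" = 1077L, "5.8S" = 157L,
  "ITS2" = 1167L, "28S" = 5070L, "3'ETS" = 361L, "IGS" = 29642L
)

# Default per-unit variant rates (variants/kb relative to the reference unit),
# derived from reported anchors for human rDNA heterogeneity: pairwise unit
# divergence ~130 variants over a ~43 kb unit (two independently mutated
# copies accumulate both variant sets), IGS density about twice the
# transcribed region, 28S the hottest mature rRNA (~4.1-5 variants/kb in
# pairwise comparisons => ~2.07/kb per unit), essentially none in 18S and
# none at all in 5.8S.
NOR_DEFAULT_RATES <- c(
  "5'ETS" = 0.225, "18S" = 0.045, "ITS1" = 0.225, "5.8S" = 0,
  "ITS2" = 0.225, "28S" = 2.07, "3'ETS" = 0.225, "IGS" = 1.8
)

#' Specification of a synthetic NOR
#'
#' @param n_units Number of tandem rDNA units (>= 1).
#' @param scale Linear scale factor applied to all default lengths and planted
#'   site offsets (e.g. `0.1` gives ~4.3 kb units for fast tests).
#' @param pj_length,dj_length Flank lengths in bp (defaults scale with
#'   `scale`).
#' @param region_lengths Named integer vector over
#'   `5'ETS, 18S, ITS1, 5.8S, ITS2, 28S, 3'ETS, IGS`.
#' @param variant_rate Named numeric vector of per-region variants/kb (per
#'   unit, relative to the reference unit template).
#' @param indel_fraction Proportion of variants that are indels.
#' @param indel_max Maximum indel length (bp).
#' @param indel_mean Mean of the (truncated geometric) indel length
#'   distribution.
#' @param gc_content Background GC fraction.
#' @param planted_sites Named list (enzyme name -> list with integer vectors
#'   `pj` and/or `dj` of flank-local 1-based positions) of restriction sites
#'   to plant.  Defaults plant EcoRV and ApaLI sites in both flanks only.
#' @param enzyme_motifs Named character vector mapping planted enzyme names to
#'   motifs; defaults come from [default_enzymes()].
#' @param seed Integer seed; identical (spec, seed) yields identical output.
#' @return A `nor_spec` list.
#' @export
nor_spec <- function(n_units = 2, scale = 1,
                     pj_length = NULL, dj_length = NULL,
                     region_lengths = NULL, variant_rate = NOR_DEFAULT_RATES,
                     indel_fraction = 0.15, indel_max = 20L, indel_mean = 3,
                     gc_content = 0.55, planted_sites = NULL,
                     enzyme_motifs = NULL, seed = 1L) {
  if (is.null(region_lengths))
    region_lengths <- pmax(1L, as.integer(round(NOR_REGION_LENGTHS * scale)))
  names(region_lengths) <- NOR_REGIONS
  if (is.null(pj_length)) pj_length <- max(50L, as.integer(round(8000 * scale)))
  if (is.null(dj_length)) dj_length <- max(50L, as.integer(round(18000 * scale)))
  if (is.null(planted_sites)) {
    planted_sites <- list(
      EcoRV = list(pj = sort(unique(pmax(1L, c(as.integer(round(pj_length * 0.1)),
                                               pj_length - as.integer(round(6249 * scale)))))),
                   dj = sort(unique(pmin(dj_length - 7L,
                                         c(as.integer(round(16278 * scale)),
                                           as.integer(round(dj_length * 0.95))))))),
      ApaLI = list(pj = pmax(1L, pj_length - as.integer(round(2000 * scale))),
                   dj = pmin(dj_length - 7L, as.integer(round(6000 * scale))))
    )
  }
  if (is.null(enzyme_motifs)) {
    tab <- default_enzymes()
    enzyme_motifs <- setNames(tab$motif, tab$name)
  }
  spec <- structure(list(
    n_units = as.integer(n_units), pj_length = as.integer(pj_length),
    dj_length = as.integer(dj_length), region_lengths = region_lengths,
    variant_rate = variant_rate[NOR_REGIONS], indel_fraction = indel_fraction,
    indel_max = as.integer(indel_max), indel_mean = indel_mean,
    gc_content = gc_content, planted_sites = planted_sites,
    enzyme_motifs = enzyme_motifs, seed = as.integer(seed)
  ), class = "nor_spec")
  validate_nor_spec(spec)
  spec
}

validate_nor_spec <- function(spec) {
  stopifnot(spec$n_units >= 1, spec$pj_length > 0, spec$dj_length > 0,
            all(spec$region_lengths > 0),
            all(!is.na(spec$variant_rate)), all(spec$variant_rate >= 0),
            spec$indel_fraction >= 0, spec$indel_fraction <= 1,
            spec$indel_max >= 1, spec$indel_max <= 20,
            spec$gc_content >= 0, spec$gc_content <= 1)
  if (!setequal(names(spec$region_lengths), NOR_REGIONS))
    stop("region_lengths must cover exactly: ", paste(NOR_REGIONS, collapse = ", "))
  for (nm in names(spec$planted_sites)) {
    if (is.null(spec$enzyme_motifs[[nm]]))
      stop("no motif known for planted enzyme ", nm)
    k <- nchar(spec$enzyme_motifs[[nm]])
    ps <- spec$planted_sites[[nm]]
    if (!is.null(ps$pj) && any(ps$pj < 1 | ps$pj + k - 1 > spec$pj_length))
      stop("planted ", nm, " PJ position outside the PJ flank")
    if (!is.null(ps$dj) && any(ps$dj < 1 | ps$dj + k - 1 > spec$dj_length))
      stop("planted ", nm, " DJ position outside the DJ flank")
  }
  invisible(spec)
}

unit_length <- function(spec) sum(spec$region_lengths)

# region annotation of a single unit in unit-local coordinates
unit_annotation <- function(spec) {
  len <- spec$region_lengths
  ends <- cumsum(len)
  data.frame(region = NOR_REGIONS,
             start = as.integer(c(1L, head(ends, -1) + 1L)),
             end = as.integer(ends), stringsAsFactors = FALSE)
}

# truncated-geometric indel lengths (mean ~ indel_mean before truncation)
draw_indel_lengths <- function(n, mean_len, max_len) {
  if (n == 0) return(integer(0))
  p <- 1 / mean_len
  len <- stats::rgeom(n, p) + 1L
  pmin(len, as.integer(max_len))
}

# left-normalize a variant against the reference sequence (VCF-style shifting
# of indels to their leftmost equivalent placement)
normalize_variant <- function(ref_seq, pos, type, ref, alt) {
  if (type == "SNV") return(list(pos = pos, ref = ref, alt = alt))
  if (type == "DEL") {
    l <- nchar(ref)
    while (pos > 1 && substr(ref_seq, pos - 1, pos - 1) ==
           substr(ref_seq, pos + l - 1, pos + l - 1)) {
      pos <- pos - 1
    }
    return(list(pos = pos, ref = substr(ref_seq, pos, pos + l - 1), alt = ""))
  }
  # INS: `pos` is the reference base after which the insertion occurs (0 = at
  # the very start); rotate the inserted string leftwards while its last base
  # equals the reference base at `pos`.
  while (pos >= 1 && substr(alt, nchar(alt), nchar(alt)) ==
         substr(ref_seq, pos, pos)) {
    alt <- paste0(substr(alt, nchar(alt), nchar(alt)),
                  substr(alt, 1, nchar(alt) - 1))
    pos <- pos - 1
  }
  list(pos = pos, ref = "", alt = alt)
}

#' Mutate a reference rDNA unit at per-region rates
#'
#' Draws SNVs and single contiguous indel events uniformly within each
#' annotated region at its Poisson rate, applies them, and returns the mutated
#' sequence together with left-aligned truth records in reference-unit
#' coordinates.
#'
#' @param reference_unit Reference unit DNA (character scalar).
#' @param annotation Data frame `region`, `start`, `end` in unit coordinates.
#' @param rates Named variants/kb per region.
#' @param indel_fraction Proportion of variants drawn as indels.
#' @param indel_mean,indel_max Indel length distribution (truncated geometric).
#' @param seed Optional integer seed.
#' @param forbid_motifs Character vector of motifs that must not occur (either
#'   strand) in the mutated unit; offending variants are locally re-drawn.
#' @param max_retries Bound on local re-draws before erroring.
#' @return List with `sequence` (mutated unit) and `variants` (data frame
#'   `pos`, `type`, `ref`, `alt`, `region`).
#' @export
mutate_unit <- function(reference_unit, annotation, rates,
                        indel_fraction = 0.15, indel_mean = 3, indel_max = 20L,
                        seed = NULL, forbid_motifs = character(0),
                        max_retries = 100L) {
  with_seed(seed, {
    L <- nchar(reference_unit)
    miss <- setdiff(annotation$region, names(rates))
    if (length(miss)) stop("no rate defined for region(s): ",
                           paste(miss, collapse = ", "))
    zlen <- annotation$end - annotation$start + 1 <= 0
    if (any(zlen & rates[annotation$region] > 0))
      stop("region with positive rate but zero length")

    draw_events <- function() {
      ev <- list()
      for (i in seq_len(nrow(annotation))) {
        reg <- annotation$region[i]
        rlen <- annotation$end[i] - annotation$start[i] + 1
        n <- rpois(1, rates[[reg]] * rlen / 1000)
        if (n == 0) next
        for (j in seq_len(n)) ev[[length(ev) + 1L]] <- draw_one(i)
      }
      ev
    }
    draw_one <- function(region_idx) {
      rs <- annotation$start[region_idx]; re <- annotation$end[region_idx]
      reg <- annotation$region[region_idx]
      is_indel <- runif(1) < indel_fraction
      if (!is_indel) {
        pos <- sample.int(re - rs + 1, 1) + rs - 1
        refb <- substr(reference_unit, pos, pos)
        altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
        list(pos = pos, type = "SNV", ref = refb, alt = altb, region = reg,
             foot = c(pos, pos))
      } else if (runif(1) < 0.5) {
        len <- draw_indel_lengths(1, indel_mean, indel_max)
        len <- min(len, re - rs)  # keep the deletion inside its region
        if (len < 1) return(draw_one(region_idx))
        pos <- sample.int(re - rs + 2 - len, 1) + rs - 1
        list(pos = pos, type = "DEL",
             ref = substr(reference_unit, pos, pos + len - 1), alt = "",
             region = reg, foot = c(pos, pos + len - 1))
      } else {
        len <- draw_indel_lengths(1, indel_mean, indel_max)
        pos <- sample.int(re - rs + 1, 1) + rs - 1  # insert after `pos`
        list(pos = pos, type = "INS", ref = "",
             alt = random_dna(len, gc = 0.5), region = reg,
             foot = c(pos, pos + 1))
      }
    }
    non_overlapping <- function(ev) {
      if (length(ev) < 2) return(ev)
      ord <- order(vapply(ev, function(e) e$foot[1], numeric(1)))
      ev <- ev[ord]
      for (tries in seq_len(max_retries)) {
        ok <- TRUE
        for (i in seq_along(ev)[-1]) {
          if (ev[[i]]$foot[1] <= ev[[i - 1]]$foot[2] + 1) {
            ri <- match(ev[[i]]$region, annotation$region)
            ev[[i]] <- draw_one(ri)
            ok <- FALSE
          }
        }
        ord <- order(vapply(ev, function(e) e$foot[1], numeric(1)))
        ev <- ev[ord]
        if (ok) return(ev)
      }
      stop("could not place non-overlapping variants after ", max_retries,
           " retries")
    }
    apply_events <- function(ev) {
      s <- reference_unit
      if (!length(ev)) return(s)
      for (e in rev(ev)) {  # right-to-left so positions stay valid
        if (e$type == "SNV") {
          substr(s, e$pos, e$pos) <- e$alt
        } else if (e$type == "DEL") {
          s <- paste0(substr(s, 1, e$pos - 1),
                      substr(s, e$pos + nchar(e$ref), nchar(s)))
        } else {
          s <- paste0(substr(s, 1, e$pos), e$alt,
                      substr(s, e$pos + 1, nchar(s)))
        }
      }
      s
    }
    motif_hits <- function(s) {
      hits <- integer(0)
      for (m in forbid_motifs) {
        sm <- scan_sites(s, list(name = m, motif = m))
        hits <- c(hits, sm$positions)
      }
      sort(unique(hits))
    }

    ev <- non_overlapping(draw_events())
    seq_out <- apply_events(ev)
    if (length(forbid_motifs)) {
      k <- max(nchar(forbid_motifs))
      for (tries in seq_len(max_retries)) {
        hits <- motif_hits(seq_out)
        if (!length(hits)) break
        # map each hit back to nearby variants (mutated coords ~ reference
        # coords within the cumulative indel shift; use a generous window)
        shift <- sum(vapply(ev, function(e)
          nchar(e$alt) - nchar(e$ref), numeric(1)))
        win <- abs(shift) + k + as.integer(indel_max) + 2L
        offenders <- vapply(ev, function(e)
          any(abs(e$foot[1] - hits) <= win | abs(e$foot[2] - hits) <= win),
          logical(1))
        if (!any(offenders)) offenders[sample.int(length(ev), 1)] <- TRUE
        for (i in which(offenders)) {
          ri <- match(ev[[i]]$region, annotation$region)
          ev[[i]] <- draw_one(ri)
        }
        ev <- non_overlapping(ev)
        seq_out <- apply_events(ev)
        if (tries == max_retries)
          stop("could not avoid forbidden motifs after ", max_retries,
               " retries")
      }
    }

    variants <- if (length(ev)) {
      rows <- lapply(ev, function(e) {
        nv <- normalize_variant(reference_unit, e$pos, e$type, e$ref, e$alt)
        data.frame(pos = nv$pos, type = e$type, ref = nv$ref, alt = nv$alt,
                   region = e$region, stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, rows)
      out[order(out$pos, out$type), , drop = FALSE]
    } else {
      data.frame(pos = integer(0), type = character(0), ref = character(0),
                 alt = character(0), region = character(0),
                 stringsAsFactors = FALSE)
    }
    rownames(variants) <- NULL
    list(sequence = seq_out, variants = variants)
  })
}

# remove every occurrence (either strand) of the given motifs from a sequence
# by resampling the offending windows; scans iteratively until clean
scrub_motifs <- function(s, motifs, gc, max_iter = 50L) {
  for (it in seq_len(max_iter)) {
    dirty <- FALSE
    for (m in motifs) {
      sm <- scan_sites(s, list(name = m, motif = m))
      for (p in sm$positions) {
        substr(s, p, p + nchar(m) - 1) <- random_dna(nchar(m), gc)
        dirty <- TRUE
      }
    }
    if (!dirty) return(s)
  }
  stop("could not scrub forbidden motifs after ", max_iter, " passes")
}

#' Build a synthetic NOR with ground truth
#'
#' Emits PJ + n mutated copies of a reference unit + DJ, plants the requested
#' restriction sites in the flanks, and guarantees that no planted enzyme has
#' a site overlapping the unit array (the design property that makes the
#' array releasable as a single fragment).
#'
#' @param spec A [nor_spec()].
#' @return A `nor_instance`: list with `sequence`, `annotation` (1-based
#'   inclusive, tiling the sequence), `truth_variants` (per unit, reference
#'   coordinates), `planted_site_positions`, `reference_unit`, `units`,
#'   `truth_fragments` (innermost-site fragment per planted enzyme), `spec`.
#' @export
build_nor <- function(spec) {
  validate_nor_spec(spec)
  with_seed(spec$seed, {
    ulen <- unit_length(spec)
    uann <- unit_annotation(spec)
    motifs <- unname(spec$enzyme_motifs[names(spec$planted_sites)])
    pj <- random_dna(spec$pj_length, spec$gc_content)
    dj <- random_dna(spec$dj_length, spec$gc_content)
    template <- random_dna(ulen, spec$gc_content)
    # scrub the template including its tandem self-junction, then the
    # flank/array junctions, so no forbidden motif can straddle a boundary
    k <- max(nchar(motifs))
    template <- scrub_motifs(template, motifs, spec$gc_content)
    for (it in 1:50) {
      junc <- paste0(substr(template, ulen - k + 2, ulen),
                     substr(template, 1, k - 1))
      hit <- any(vapply(motifs, function(m)
        length(scan_sites(junc, list(name = m, motif = m))$positions) > 0,
        logical(1)))
      if (!hit) break
      substr(template, 1, k - 1) <- random_dna(k - 1, spec$gc_content)
      template <- scrub_motifs(template, motifs, spec$gc_content)
    }

    unit_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_units)
    units <- vector("list", spec$n_units)
    truth <- vector("list", spec$n_units)
    for (u in seq_len(spec$n_units)) {
      mu <- mutate_unit(template, uann, spec$variant_rate,
                        indel_fraction = spec$indel_fraction,
                        indel_mean = spec$indel_mean,
                        indel_max = spec$indel_max,
                        seed = unit_seeds[u], forbid_motifs = motifs)
      units[[u]] <- mu$sequence
      tv <- mu$variants
      if (nrow(tv)) tv$unit <- u
      truth[[u]] <- tv
    }
    truth_variants <- do.call(rbind, truth[vapply(truth, nrow, 1L) > 0])
    if (is.null(truth_variants))
      truth_variants <- data.frame(pos = integer(0), type = character(0),
                                   ref = character(0), alt = character(0),
                                   region = character(0), unit = integer(0),
                                   stringsAsFactors = FALSE)
    rownames(truth_variants) <- NULL

    # junctions between consecutive (mutated) units and with the flanks must
    # also be free of forbidden motifs; fix flank bases (never unit bases, so
    # truth variants stay valid)
    array_seq <- paste(unlist(units), collapse = "")
    pj <- fix_junction_flank(pj, array_seq, motifs, spec$gc_content, side = "pj")
    dj <- fix_junction_flank(dj, array_seq, motifs, spec$gc_content, side = "dj")
    # unit-unit junctions: both sides are mutated template; a motif can arise
    # there only via near-junction variants, which mutate_unit already screens
    # (it scans each full unit, and the scrubbed template junction covers the
    # unmutated case).  Verify and redraw the downstream unit if needed.
    guard <- k - 1L
    for (it in 1:50) {
      array_seq <- paste(unlist(units), collapse = "")
      full <- paste0(pj, array_seq, dj)
      arr_start <- spec$pj_length + 1L
      arr_end <- spec$pj_length + nchar(array_seq)
      window <- substr(full, arr_start - guard, arr_end + guard)
      hits <- integer(0)
      kk <- 0L
      for (m in motifs) {
        hp <- scan_sites(window, list(name = m, motif = m))$positions
        if (length(hp)) { hits <- c(hits, hp); kk <- max(kk, nchar(m)) }
      }
      if (!length(hits)) break
      if (it == 50) stop("planted motif keeps re-arising inside the array")
      h <- min(hits)
      h_start <- arr_start - guard - 1L + h          # global motif start
      h_end <- h_start + kk - 1L
      if (h_start < arr_start) {
        pj <- fix_junction_flank(pj, array_seq, motifs, spec$gc_content, "pj")
      } else if (h_end > arr_end) {
        dj <- fix_junction_flank(dj, array_seq, motifs, spec$gc_content, "dj")
      } else {
        # redraw the unit containing (or starting at) the hit
        upos <- h_start - spec$pj_length
        cum <- cumsum(vapply(units, nchar, 1L))
        u <- which(upos <= cum)[1]
        if (is.na(u)) u <- spec$n_units
        mu <- mutate_unit(template, uann, spec$variant_rate,
                          indel_fraction = spec$indel_fraction,
                          indel_mean = spec$indel_mean,
                          indel_max = spec$indel_max,
                          seed = sample.int(.Machine$integer.max - 1L, 1),
                          forbid_motifs = motifs)
        units[[u]] <- mu$sequence
        tv <- mu$variants
        if (nrow(tv)) tv$unit <- u
        truth_variants <- truth_variants[truth_variants$unit != u, , drop = FALSE]
        truth_variants <- rbind(truth_variants, tv)
      }
    }
    truth_variants <- truth_variants[order(truth_variants$unit,
                                           truth_variants$pos), , drop = FALSE]
    rownames(truth_variants) <- NULL

    # plant the requested sites in the flanks
    planted <- list()
    for (nm in names(spec$planted_sites)) {
      motif <- spec$enzyme_motifs[[nm]]
      ps <- spec$planted_sites[[nm]]
      gpos <- integer(0)
      if (!is.null(ps$pj))
        for (p in ps$pj) { substr(pj, p, p + nchar(motif) - 1) <- motif
                           gpos <- c(gpos, p) }
      if (!is.null(ps$dj))
        for (p in ps$dj) {
          substr(dj, p, p + nchar(motif) - 1) <- motif
          gpos <- c(gpos, spec$pj_length + nchar(array_seq) + p)
        }
      planted[[nm]] <- sort(gpos)
    }

    array_seq <- paste(unlist(units), collapse = "")
    sequence <- paste0(pj, array_seq, dj)

    # annotation tiling the full sequence
    rows <- list(data.frame(region = "PJ", unit = 0L, start = 1L,
                            end = spec$pj_length, stringsAsFactors = FALSE))
    offset <- spec$pj_length
    for (u in seq_len(spec$n_units)) {
      ul <- nchar(units[[u]])
      # per-unit region boundaries track the mutated unit's own coordinates:
      # rescale reference boundaries by the indel shifts inside each region
      uv <- truth_variants[truth_variants$unit == u, , drop = FALSE]
      bnds <- unit_region_bounds(uann, uv)
      rows[[length(rows) + 1L]] <-
        data.frame(region = uann$region, unit = u,
                   start = offset + bnds$start, end = offset + bnds$end,
                   stringsAsFactors = FALSE)
      offset <- offset + ul
    }
    rows[[length(rows) + 1L]] <-
      data.frame(region = "DJ", unit = 0L, start = offset + 1L,
                 end = offset + spec$dj_length, stringsAsFactors = FALSE)
    annotation <- do.call(rbind, rows)
    rownames(annotation) <- NULL

    nor <- structure(list(sequence = sequence, annotation = annotation,
                          truth_variants = truth_variants,
                          planted_site_positions = planted,
                          reference_unit = template, units = units,
                          spec = spec), class = "nor_instance")
    # ground-truth released fragment per planted enzyme
    arr <- array_interval(nor)
    nor$truth_fragments <- lapply(names(planted), function(nm) {
      sm <- scan_sites(sequence, list(name = nm, motif = spec$enzyme_motifs[[nm]]))
      predict_fragments(sm, nchar(sequence), arr)
    })
    names(nor$truth_fragments) <- names(planted)
    nor
  })
}

# resample flank bases adjacent to the array until no forbidden motif
# straddles the flank/array junction (unit bases are never touched)
fix_junction_flank <- function(flank, array_seq, motifs, gc, side,
                               max_iter = 50L) {
  k <- max(nchar(motifs))
  for (it in seq_len(max_iter)) {
    junc <- if (side == "pj") {
      paste0(substr(flank, nchar(flank) - k + 2, nchar(flank)),
             substr(array_seq, 1, k - 1))
    } else {
      paste0(substr(array_seq, nchar(array_seq) - k + 2, nchar(array_seq)),
             substr(flank, 1, k - 1))
    }
    hit <- any(vapply(motifs, function(m)
      length(scan_sites(junc, list(name = m, motif = m))$positions) > 0,
      logical(1)))
    if (!hit) return(flank)
    if (side == "pj") {
      substr(flank, nchar(flank) - k + 2, nchar(flank)) <- random_dna(k - 1, gc)
    } else {
      substr(flank, 1, k - 1) <- random_dna(k - 1, gc)
    }
  }
  stop("could not clear flank/array junction of forbidden motifs")
}

# region boundaries of a mutated unit in its own coordinates, obtained by
# shifting reference boundaries by the net indel length to their left
unit_region_bounds <- function(uann, variants) {
  shift_at <- function(ref_pos) {
    if (!nrow(variants)) return(0L)
    ins <- variants[variants$type == "INS" & variants$pos < ref_pos, , drop = FALSE]
    del <- variants[variants$type == "DEL" & variants$pos <= ref_pos, , drop = FALSE]
    # deletions overlapping the boundary shorten only up to the boundary
    dlen <- 0L
    if (nrow(del)) {
      dend <- del$pos + nchar(del$ref) - 1L
      dlen <- sum(pmin(dend, ref_pos) - del$pos + 1L)
    }
    as.integer(sum(nchar(ins$alt)) - dlen)
  }
  ends <- vapply(uann$end, function(e) e + shift_at(e), integer(1))
  starts <- c(1L, head(ends, -1) + 1L)
  data.frame(start = starts, end = ends)
}

#' @export
print.nor_instance <- function(x, ...) {
  cat(sprintf("<nor_instance> %d bp: PJ %d bp + %d unit(s) + DJ %d bp; %d truth variant(s)\n",
              nchar(x$sequence), x$spec$pj_length, x$spec$n_units,
              x$spec$dj_length, nrow(x$truth_variants)))
  invisible(x)
}

#' Simulate a circular TAR clone and its linearized emission
#'
#' Digests the NOR with the given enzyme, requires that a single fragment
#' containing the whole unit array is released, captures it in a circular
#' vector+insert molecule, and emits a random rotation of the circle with an
#' appended duplicated terminal segment (the "circular overlap" a long-read
#' assembler leaves on a circular molecule).
#'
#' @param nor A `nor_instance`.
#' @param enzyme Enzyme name/motif (see [scan_sites()]).
#' @param vector_seq Vector sequence; default: random 8 kb (scaled).
#' @param rotation Rotation offset for linearization; default random.
#' @param circular_overlap Length (bp) of the duplicated terminal segment.
#' @param hook_length_range Hook length bounds passed to [design_hooks()].
#' @param seed Optional integer seed.
#' @return A `clone_template`: list with `emission`, `insert` (truth),
#'   `vector`, `hook5`, `hook3`, `rotation`, `circular_overlap`, `fragment`.
#' @export
simulate_clone <- function(nor, enzyme, vector_seq = NULL, rotation = NULL,
                           circular_overlap = 500L,
                           hook_length_range = c(170, 200), seed = NULL) {
  with_seed(seed, {
    enz <- enzyme_record(enzyme)
    if (enz$name %in% names(nor$spec$enzyme_motifs))
      enz$motif <- nor$spec$enzyme_motifs[[enz$name]]
    sm <- scan_sites(nor$sequence, enz)
    arr <- array_interval(nor)
    inside <- sm$positions[sm$positions > arr[1] & sm$positions <= arr[2]]
    if (length(inside))
      stop(enz$name, " cuts inside the unit array at position ", inside[1])
    frag <- predict_fragments(sm, nchar(nor$sequence), arr)
    insert <- subseq_chr(nor$sequence, frag$start, frag$end)
    hooks <- design_hooks(nor$sequence, c(frag$start, frag$end),
                          length_range = hook_length_range)
    if (is.null(vector_seq))
      vector_seq <- random_dna(max(200L, as.integer(round(8000 * nchar(insert) /
                                                          43000))), 0.5)
    circle <- paste0(vector_seq, insert)
    if (is.null(rotation)) rotation <- sample.int(nchar(circle), 1) - 1L
    emission <- rotate_seq(circle, rotation)
    if (circular_overlap > 0) {
      ov <- min(circular_overlap, nchar(emission) - 1L)
      emission <- paste0(emission, substr(emission, 1, ov))
    }
    structure(list(emission = emission, insert = insert, vector = vector_seq,
                   hook5 = hooks$seq5, hook3 = hooks$seq3,
                   hook5_design = hooks$hook5, hook3_design = hooks$hook3,
                   rotation = as.integer(rotation),
                   circular_overlap = as.integer(min(circular_overlap,
                                                     nchar(circle) - 1L)),
                   fragment = frag, enzyme = enz$name),
              class = "clone_template")
  })
}

#' @export
print.clone_template <- function(x, ...) {
  cat(sprintf("<clone_template> %s clone: insert %d bp + vector %d bp, rotation %d, overlap %d bp\n",
              x$enzyme, nchar(x$insert), nchar(x$vector), x$rotation,
              x$circular_overlap))
  invisible(x)
}

#' Export a NOR instance to FASTA + BED + variant TSV
#'
#' @param nor A `nor_instance`.
#' @param dir Output directory (created if missing).
#' @param name Base name for files.
#' @return Named character vector of written paths, invisibly.
#' @export
write_nor <- function(nor, dir, name = "nor") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(name, ".fa"))
  bed <- file.path(dir, paste0(name, ".bed"))
  tsv <- file.path(dir, paste0(name, "_truth_variants.tsv"))
  write_fasta(setNames(nor$sequence, name), fa)
  ann <- nor$annotation
  write_bed(data.frame(chrom = name, start = ann$start, end = ann$end,
                       name = paste0(ann$region,
                                     ifelse(ann$unit > 0,
                                            paste0("_unit", ann$unit), ""))),
            bed)
  tv <- nor$truth_variants
  write_variants(data.frame(unit = paste0("unit", tv$unit), pos = tv$pos,
                            ref = tv$ref, alt = tv$alt, type = tv$type,
                            region = tv$region), tsv)
  invisible(c(fasta = fa, bed = bed, variants = tsv))
}
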