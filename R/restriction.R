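# Restriction-site scanning, cloning-enzyme selection, targeting-hook design
# and digest fragment prediction.
#
# Cut positions are approximated by the motif start: the enzymes used for
# array release (EcoRV, ApaLI) cut within their 6-mer recognition sites, and
# all downstream uses (presence/absence inside the array, ~kb-scale band
# sizes) are insensitive to sub-motif offsets.  A per-enzyme cut offset field
# is reserved on the enzyme record but not applied.

#' Built-in restriction enzyme table
#'
#' A small screening panel; `EcoRV` (GATATC) and `ApaLI` (GTGCAC) are the
#' enzymes classically used to release intact human rDNA arrays, because their
#' sites are absent (or very rare) inside rDNA units while present in the
#' junction sequences.
#'
#' @return Data frame with columns `name`, `motif`, `cut_offset`.
#' @export
default_enzymes <- function() {
  data.frame(
    name = c("EcoRV", "ApaLI", "BamHI", "HindIII", "NotI", "SwaI", "PacI", "AscI"),
    motif = c("GATATC", "GTGCAC", "GGATCC", "AAGCTT", "GCGGCCGC",
              "ATTTAAAT", "TTAATTAA", "GGCGCGCC"),
    cut_offset = 0L,
    stringsAsFactors = FALSE
  )
}

enzyme_record <- function(enzyme, motif = NULL) {
  if (is.list(enzyme) && !is.null(enzyme$motif))
    return(list(name = enzyme$name, motif = toupper(enzyme$motif)))
  if (is.character(enzyme) && length(enzyme) == 1 && !is.null(motif))
    return(list(name = enzyme, motif = toupper(motif)))
  if (is.character(enzyme) && length(enzyme) == 1) {
    tab <- default_enzymes()
    hit <- match(enzyme, tab$name)
    if (!is.na(hit)) return(list(name = enzyme, motif = tab$motif[hit]))
    # otherwise treat the string itself as a motif
    return(list(name = enzyme, motif = toupper(enzyme)))
  }
  stop("cannot interpret enzyme specification")
}

validate_motif <- function(motif) {
  if (nchar(motif) < 4) stop("motif length must be >= 4")
  if (!is_valid_iupac(motif)) stop("invalid IUPAC letters in motif: ", motif)
  invisible(motif)
}

#' Scan a sequence for restriction sites
#'
#' Matches the motif under IUPAC ambiguity rules on both strands; `N` in the
#' subject never matches.  Palindromic motifs are reported once per locus.
#' Positions are 1-based motif starts on the forward strand.
#'
#' @param sequence DNA character scalar over `A,C,G,T,N`.
#' @param enzyme Enzyme name (looked up in [default_enzymes()]), a motif
#'   string, or a list with `name` and `motif`.
#' @return A `site_map`: list with `enzyme`, `motif`, sorted integer
#'   `positions`.
#' @export
scan_sites <- function(sequence, enzyme) {
  enz <- enzyme_record(enzyme)
  validate_motif(enz$motif)
  positions <- integer(0)
  if (nchar(sequence) >= nchar(enz$motif)) {
    subj <- Biostrings::DNAString(sequence)
    fwd <- Biostrings::matchPattern(Biostrings::DNAString(enz$motif), subj,
                                    fixed = FALSE)
    pos <- BiocGenerics::start(fwd)
    rc <- revcomp(enz$motif)
    if (rc != enz$motif) {
      rev <- Biostrings::matchPattern(Biostrings::DNAString(rc), subj,
                                      fixed = FALSE)
      pos <- c(pos, BiocGenerics::start(rev))
    }
    pos <- sort(unique(pos))
    if (length(pos)) {
      # drop hits whose subject window strays outside A/C/G/T (e.g. over N)
      k <- nchar(enz$motif)
      ok <- vapply(pos, function(p)
        !grepl("[^ACGT]", substr(sequence, p, p + k - 1)), logical(1))
      pos <- pos[ok]
    }
    positions <- as.integer(pos)
  }
  structure(list(enzyme = enz$name, motif = enz$motif, positions = positions),
            class = "site_map")
}

#' @export
print.site_map <- function(x, ...) {
  cat(sprintf("<site_map> %s (%s): %d site(s)\n", x$enzyme, x$motif,
              length(x$positions)))
  invisible(x)
}

array_interval <- function(nor) {
  units <- nor$annotation[nor$annotation$unit > 0, , drop = FALSE]
  c(min(units$start), max(units$end))
}

#' Select enzymes that release the rDNA array intact
#'
#' An enzyme qualifies when it has no recognition site overlapping the unit
#' array and at least one site in each flank.  The innermost flank sites
#' bracket the released fragment.
#'
#' @param nor A `nor_instance` from [build_nor()].
#' @param candidates Data frame with `name` and `motif` columns
#'   (default [default_enzymes()]).
#' @return Data frame of qualifying enzymes (sorted by released fragment
#'   length, ascending) with columns `name`, `motif`, `innermost5`,
#'   `innermost3`, `fragment_length`.  Empty (with a warning) when no enzyme
#'   qualifies.
#' @export
select_cloning_enzymes <- function(nor, candidates = default_enzymes()) {
  arr <- array_interval(nor)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    motif <- candidates$motif[i]
    k <- nchar(motif)
    sm <- scan_sites(nor$sequence, list(name = candidates$name[i], motif = motif))
    p <- sm$positions
    inside <- p[p <= arr[2] & (p + k - 1) >= arr[1]]
    left <- p[(p + k - 1) < arr[1]]
    right <- p[p > arr[2]]
    if (length(inside) || !length(left) || !length(right)) return(NULL)
    in5 <- max(left); in3 <- min(right)
    data.frame(name = candidates$name[i], motif = motif,
               innermost5 = in5, innermost3 = in3,
               fragment_length = in3 - in5, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    warning("no candidate enzyme releases the array intact")
    return(data.frame(name = character(0), motif = character(0),
                      innermost5 = integer(0), innermost3 = integer(0),
                      fragment_length = integer(0)))
  }
  out[order(out$fragment_length), , drop = FALSE]
}

#' Construct a targeting-hook design record
#'
#' @param side `"5'"` or `"3'"`.
#' @param start,end 1-based inclusive interval of the hook.
#' @param distance_to_cut Distance from the fragment end (bp, 0 = flush).
#' @param distance_to_array Distance to the unit array (bp), if known.
#' @return A `hook_design` with `length = end - start + 1`.
#' @export
hook_design <- function(side, start, end, distance_to_cut = 0L,
                        distance_to_array = NA_integer_) {
  stopifnot(side %in% c("5'", "3'"), end >= start, start >= 1)
  structure(list(side = side, start = as.integer(start), end = as.integer(end),
                 length = as.integer(end - start + 1L),
                 distance_to_cut = as.integer(distance_to_cut),
                 distance_to_array = distance_to_array),
            class = "hook_design")
}

#' @export
print.hook_design <- function(x, ...) {
  cat(sprintf("<hook_design> %s hook: %d-%d (%d bp), %d bp from cut\n",
              x$side, x$start, x$end, x$length, x$distance_to_cut))
  invisible(x)
}

#' Design 5' and 3' targeting hooks inside a released fragment
#'
#' Hooks are chosen immediately inside the fragment ends (distance to the cut
#' is 0 unless uniqueness forces a slide inward), with lengths inside
#' `length_range` and a single exact occurrence within the fragment.
#'
#' @param sequence Full DNA sequence containing the fragment.
#' @param fragment Integer `c(start, end)`, 1-based inclusive.
#' @param length_range Hook length bounds, default `c(170, 200)`.
#' @param search_window How far from each fragment end a hook may start
#'   (default 1000 bp).
#' @return List with elements `hook5` and `hook3` ([hook_design()] objects)
#'   plus `seq5`, `seq3` hook sequences.
#' @export
design_hooks <- function(sequence, fragment, length_range = c(170, 200),
                         search_window = 1000) {
  frag <- subseq_chr(sequence, fragment[1], fragment[2])
  nf <- nchar(frag)
  if (nf <= 2 * length_range[2])
    stop("fragment shorter than twice the maximum hook length")
  pick <- function(side) {
    for (off in 0:(search_window - length_range[1])) {
      for (len in seq(length_range[2], length_range[1])) {
        if (off + len > nf) next
        if (side == "5'") {
          s <- off + 1
        } else {
          s <- nf - off - len + 1
          if (s < 1) next
        }
        hook <- substr(frag, s, s + len - 1)
        nhit <- length(Biostrings::matchPattern(hook, Biostrings::DNAString(frag)))
        if (nhit == 1)
          return(list(start = s, len = len, off = off, seq = hook))
      }
    }
    stop("no unique ", side, " hook of length ", length_range[1], "-",
         length_range[2], " bp within ", search_window,
         " bp of the fragment end; consider widening length_range")
  }
  h5 <- pick("5'")
  h3 <- pick("3'")
  list(
    hook5 = hook_design("5'", fragment[1] + h5$start - 1,
                        fragment[1] + h5$start + h5$len - 2,
                        distance_to_cut = h5$off),
    hook3 = hook_design("3'", fragment[1] + h3$start - 1,
                        fragment[1] + h3$start + h3$len - 2,
                        distance_to_cut = h3$off),
    seq5 = h5$seq, seq3 = h3$seq
  )
}

#' Predict the digest fragment containing a query interval
#'
#' Fragment boundaries are placed at motif starts; the fragment containing the
#' query (e.g. the unit array) corresponds to the band observed after
#' digestion and pulsed-field separation.
#'
#' @param sitemap A `site_map` from [scan_sites()].
#' @param seq_length Total sequence length.
#' @param query Integer `c(start, end)` that must lie within one fragment.
#' @return List with `start`, `end`, `length`.
#' @export
predict_fragments <- function(sitemap, seq_length, query) {
  stopifnot(inherits(sitemap, "site_map"))
  p <- sitemap$positions
  spanning <- p[p > query[1] & p <= query[2]]
  if (length(spanning))
    stop("query interval spans a ", sitemap$enzyme, " site at position ",
         spanning[1], "; array not released intact")
  bounds <- c(1L, p[p <= query[1]], p[p > query[2]], seq_length + 1L)
  left <- max(bounds[bounds <= query[1]])
  right <- min(bounds[bounds > query[2]])
  list(start = left, end = right - 1L, length = right - left)
}
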