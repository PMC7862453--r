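# File formats: FASTA (via Biostrings), BED (0-based half-open on disk,
# 1-based inclusive in memory), VCF-like variant TSV, enzyme tables, qPCR Ct
# tables, and JSON run configuration.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on read.  Duplicate record ids and non-IUPAC
#' characters are errors; the error for an invalid character names the record
#' and 1-based offset of the first offending letter.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    bad <- regexpr(paste0("[^", paste(IUPAC_LETTERS, collapse = ""), "]"), seqs[[i]])
    if (bad > 0)
      stop(sprintf("non-IUPAC character '%s' in record '%s' at offset %d",
                   substr(seqs[[i]], bad, bad), ids[i], as.integer(bad)))
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param records Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (length(records) == 0) stop("no records to write")
  if (is.null(names(records)) || any(names(records) == ""))
    stop("all records must be named")
  if (anyDuplicated(names(records))) stop("duplicate record ids")
  set <- Biostrings::BStringSet(toupper(records))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Write an annotation table as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' `start` is decremented on write and incremented on read.
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(df)))
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    name = df$name)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file into 1-based inclusive coordinates
#' @param path BED path (first four columns used).
#' @return Data frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED needs at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]),
                    name = if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_,
                    stringsAsFactors = FALSE)
  bad <- which(out$end < out$start)
  if (length(bad))
    stop("malformed interval at line ", bad[1])
  out
}

#' Write variant records as a VCF-like TSV
#'
#' Columns: CHROM (unit id), POS (1-based on the reference unit), REF, ALT,
#' TYPE (SNV/INS/DEL), REGION.
#'
#' @param variants Data frame with columns `unit`, `pos`, `ref`, `alt`,
#'   `type`, `region`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  out <- data.frame(CHROM = variants$unit, POS = variants$pos,
                    REF = variants$ref, ALT = variants$alt,
                    TYPE = variants$type, REGION = variants$region)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a VCF-like variant TSV written by [write_variants()]
#' @param path Input path.
#' @return Data frame with `unit`, `pos`, `ref`, `alt`, `type`, `region`.
#' @export
read_variants <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(REF = "character", ALT = "character"))
  df$REF[is.na(df$REF)] <- ""
  df$ALT[is.na(df$ALT)] <- ""
  data.frame(unit = df$CHROM, pos = df$POS, ref = df$REF, alt = df$ALT,
             type = df$TYPE, region = df$REGION, stringsAsFactors = FALSE)
}

#' Read an enzyme table (TSV with columns `name`, `motif`)
#' @param path Input path.
#' @return Data frame of enzymes.
#' @export
read_enzymes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "motif") %in% names(df)))
  df$motif <- toupper(df$motif)
  df
}

#' Read a qPCR Ct table (TSV)
#'
#' Expected columns: `sample`, `amplicon`, `type` ("target" or "control"),
#' `replicate`, `ct`.
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_ct_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "amplicon", "type", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  df
}
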