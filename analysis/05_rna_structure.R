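#!/usr/bin/env Rscript
# Score transcribed-region SNVs for structural impact: fold windows around
# each variant for both alleles, compute the structural index D and the
# change in opening penalty, the randomization empirical P and z-score, and
# the MWW comparison of the alleles' opening-penalty profiles.

suppressPackageStartupMessages(library(norkit))
dir.create("results", showWarnings = FALSE)

ref <- read_fasta("results/nor/reference_unit.fa")[[1]]
calls <- read_variants("results/called_variants.tsv")
tx <- calls[calls$region %in% c("18S", "28S", "5.8S") & calls$type == "SNV", ]
tx <- tx[!duplicated(paste(tx$pos, tx$alt)), ]
tx <- head(tx, 5)  # a handful of mature-rRNA SNVs

fp <- fold_params(model = "stacks", windows = c(100L))
rows <- list()
for (i in seq_len(nrow(tx))) {
  v <- as.list(tx[i, c("pos", "type", "ref", "alt")])
  w <- 100L
  ws <- max(1L, v$pos - w %/% 2L)
  ref_win <- substr(ref, ws, min(nchar(ref), ws + w - 1L))
  v_local <- v; v_local$pos <- v$pos - ws + 1L
  alt_win <- apply_variant(ref_win, v_local)
  imp <- call_ribosnitch(ref_win, alt_win, fp, n_rand = 100, seed = 400 + i)
  rows[[i]] <- cbind(data.frame(region = tx$region[i], pos = v$pos,
                                ref = v$ref, alt = v$alt),
                     imp$windows, ribosnitch = imp$ribosnitch)
}
impact <- do.call(rbind, rows)
print(impact, row.names = FALSE)
write.table(impact, "results/structure_impact.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\n%d of %d scored SNVs flagged as potential riboSNitches\n",
            sum(impact$ribosnitch), nrow(impact)))
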