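#!/usr/bin/env Rscript
# Screen the enzyme panel against the simulated NOR, pick the enzymes that
# release the intact rDNA array, predict the digest band a pulsed-field gel
# would show, and design the TAR targeting hooks flanking the cut sites.

suppressPackageStartupMessages(library(norkit))
dir.create("results", showWarnings = FALSE)

nor_seq <- read_fasta("results/nor/nor_chr22.fa")[[1]]
bed <- read_bed("results/nor/nor_chr22.bed")
units <- bed[grepl("unit", bed$name), ]
arr <- c(min(units$start), max(units$end))

panel <- read_enzymes(system.file("extdata", "enzymes.tsv", package = "norkit"))
rows <- list()
for (i in seq_len(nrow(panel))) {
  sm <- scan_sites(nor_seq, list(name = panel$name[i], motif = panel$motif[i]))
  p <- sm$positions
  k <- nchar(panel$motif[i])
  inside <- sum(p <= arr[2] & p + k - 1 >= arr[1])
  ok <- inside == 0 && any(p + k - 1 < arr[1]) && any(p > arr[2])
  band <- if (ok) predict_fragments(sm, nchar(nor_seq), arr)$length else NA
  rows[[i]] <- data.frame(enzyme = panel$name[i], motif = panel$motif[i],
                          n_sites = length(p), sites_in_array = inside,
                          releases_array = ok, band_bp = band)
}
design <- do.call(rbind, rows)
write.table(design, "results/restriction_design.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(design, row.names = FALSE)

for (enz in design$enzyme[design$releases_array]) {
  sm <- scan_sites(nor_seq, enz)
  frag <- predict_fragments(sm, nchar(nor_seq), arr)
  hk <- design_hooks(nor_seq, c(frag$start, frag$end))
  cat(sprintf("%s: band %.1f kb; 5' hook %d bp at %d-%d; 3' hook %d bp at %d-%d\n",
              enz, frag$length / 1000, hk$hook5$length, hk$hook5$start,
              hk$hook5$end, hk$hook3$length, hk$hook3$start, hk$hook3$end))
}
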