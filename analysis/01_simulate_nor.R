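#!/usr/bin/env Rscript
# Simulate the study system: a full-scale synthetic NOR for "chromosome 22"
# (two ~43 kb rDNA units between PJ and DJ flanks) plus an independent set of
# units from a second "chromosome 21" sharing the same reference unit, so
# that cross-chromosome sharing is defined.  Writes FASTA/BED/truth tables
# under results/nor/.

suppressPackageStartupMessages(library(norkit))
out <- "results/nor"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- nor_spec(n_units = 2, scale = 1, seed = 20260901)
nor <- build_nor(spec)
write_nor(nor, out, "nor_chr22")
write_fasta(setNames(nor$reference_unit, "reference_unit"),
            file.path(out, "reference_unit.fa"))

# units for a second chromosome, mutated from the same reference unit
uann <- norkit:::unit_annotation(spec)
units21 <- lapply(1:2, function(i)
  mutate_unit(nor$reference_unit, uann, spec$variant_rate,
              indel_fraction = spec$indel_fraction, seed = 3100 + i))
write_fasta(setNames(vapply(units21, `[[`, "", "sequence"),
                     paste0("chr21_unit", 1:2)),
            file.path(out, "chr21_units.fa"))

cat(sprintf("NOR: %d bp (%d units of %d bp); %d truth variants\n",
            nchar(nor$sequence), spec$n_units, norkit:::unit_length(spec),
            nrow(nor$truth_variants)))
cat(sprintf("per-region truth densities (variants/kb, both units pooled):\n"))
tv <- nor$truth_variants
for (r in norkit:::NOR_REGIONS) {
  len <- spec$region_lengths[[r]] * spec$n_units
  cat(sprintf("  %-6s %5.2f\n", r, sum(tv$region == r) / (len / 1000)))
}
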