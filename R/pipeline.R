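# Run configuration and the end-to-end pipeline: simulate -> design -> clone
# -> finish -> merge -> variants -> structure -> copies, writing every
# intermediate and a reproducible summary report.

#' Default run configuration
#'
#' Nested list of stage parameters.  The default problem size is a 1/10-scale
#' NOR (two ~4.3 kb units per chromosome), small enough to run the whole
#' pipeline in seconds while exercising every stage.
#'
#' @param seed Global seed.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    nor = list(n_units = 2L, scale = 0.1, indel_fraction = 0.15,
               gc_content = 0.55),
    second_chromosome = list(enabled = TRUE, n_units = 2L),
    clone = list(enzyme = "EcoRV", circular_overlap = 500L),
    hooks = list(length_min = 170L, length_max = 200L),
    variants = list(match = 1, mismatch = -2, gap_open = -5, gap_extend = -1,
                    band = 200L),
    structure = list(model = "pairmax", windows = c(100L), n_rand = 49L,
                     alpha = 0.05),
    qpcr = list(copies = 16, calibrator_copies = 400, n_amplicons = 4L,
                n_replicates = 3L, efficiency = 1, noise_sd = 0.2),
    log_level = "info"
  ), class = "run_config")
}

#' Validate a run configuration against the default template
#'
#' Unknown keys (at any level) and missing required fields are errors.
#'
#' @param config A configuration list.
#' @return The validated config, invisibly.
#' @export
validate_config <- function(config) {
  template <- default_config()
  check <- function(cfg, tmpl, path = "") {
    unknown <- setdiff(names(cfg), names(tmpl))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "))
    missing <- setdiff(names(tmpl), names(cfg))
    if (length(missing))
      stop("missing required config field(s): ",
           paste0(path, missing, collapse = ", "))
    for (nm in names(tmpl))
      if (is.list(tmpl[[nm]]) && !is.null(names(tmpl[[nm]])))
        check(cfg[[nm]], tmpl[[nm]], paste0(path, nm, "."))
  }
  check(config, template)
  invisible(config)
}

#' Read / write a run configuration as JSON
#' @param path JSON path.
#' @return The configuration list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- structure(cfg, class = "run_config")
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full synthetic NOR pipeline
#'
#' Simulates a NOR (and optionally a second "chromosome" from the same
#' reference unit), selects a cloning enzyme, designs hooks, simulates and
#' finishes a circular clone, merges a PJ-side clone with the array clone
#' into a contig, calls variants per unit, computes divergence/sharing/
#' density statistics, scores the first transcribed-region variant as a
#' riboSNitch, estimates copy number from simulated qPCR, and writes all
#' intermediates plus a JSON report to `out_dir`.
#'
#' @param config A `run_config` (see [default_config()]).
#' @param out_dir Output directory.
#' @return The report list, invisibly readable from `report.json`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("norkit_run_")) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, 10))
  report <- list(seed = config$seed, stage_seeds = seeds)

  # 1. simulate
  spec <- nor_spec(n_units = config$nor$n_units, scale = config$nor$scale,
                   indel_fraction = config$nor$indel_fraction,
                   gc_content = config$nor$gc_content, seed = seeds[1])
  nor <- build_nor(spec)
  write_nor(nor, out_dir, "nor_chr22")
  report$nor <- list(length_bp = nchar(nor$sequence),
                     n_units = spec$n_units,
                     unit_length_bp = unit_length(spec),
                     n_truth_variants = nrow(nor$truth_variants))

  # 2. restriction design
  sel <- select_cloning_enzymes(nor)
  if (!nrow(sel)) stop("pipeline stage 'design': no qualifying enzyme")
  chosen <- config$clone$enzyme
  if (!chosen %in% sel$name) chosen <- sel$name[1]
  row <- sel[sel$name == chosen, ][1, ]
  frag <- nor$truth_fragments[[chosen]]
  hooks <- design_hooks(nor$sequence, c(frag$start, frag$end),
                        length_range = c(config$hooks$length_min,
                                         config$hooks$length_max))
  report$design <- list(enzymes_considered = nrow(default_enzymes()),
                        enzymes_selected = sel$name,
                        chosen_enzyme = chosen,
                        predicted_band_bp = frag$length,
                        hook5_length = hooks$hook5$length,
                        hook3_length = hooks$hook3$length)

  # 3. clone simulation + finishing
  clone <- simulate_clone(nor, chosen,
                          circular_overlap = config$clone$circular_overlap,
                          seed = seeds[2])
  fin <- finish_assembly(clone$emission, clone$vector,
                         hooks = c(hook5 = clone$hook5, hook3 = clone$hook3))
  write_fasta(c(clone_assembly = clone$emission, finished_insert = fin$insert),
              file.path(out_dir, "clone.fa"))
  report$finishing <- list(insert_bp = nchar(fin$insert),
                           insert_recovered_exactly =
                             identical(fin$insert, clone$insert),
                           circular_overlap_removed = fin$circular_overlap_removed,
                           hooks_found = as.list(fin$hooks_found))

  # 4. contig merge: a PJ-side clone overlapping the array clone
  arr <- array_interval(nor)
  ov_target <- max(200L, min(2000L, frag$length %/% 4L))
  pj_clone <- subseq_chr(nor$sequence, 1L, frag$start + ov_target - 1L)
  mg <- merge_inserts(pj_clone, fin$insert, min_overlap = 100,
                      ids = c("PJ_clone", paste0(chosen, "_clone")))
  truth_contig <- subseq_chr(nor$sequence, 1L, frag$end)
  write_fasta(c(nor_contig = mg$contig), file.path(out_dir, "contig.fa"))
  report$merge <- list(contig_bp = nchar(mg$contig),
                       overlap_bp = mg$overlap_length,
                       mismatches = mg$mismatches_in_overlap,
                       matches_truth = identical(mg$contig, truth_contig))

  # 5. variant analysis across units (two "chromosomes" if configured)
  units <- setNames(nor$units, paste0("chr22_unit", seq_along(nor$units)))
  groups <- setNames(rep("chr22", length(units)), names(units))
  if (isTRUE(config$second_chromosome$enabled)) {
    spec2 <- spec
    spec2$n_units <- as.integer(config$second_chromosome$n_units)
    spec2$seed <- seeds[3]
    nor2 <- build_nor(spec2)
    # second chromosome shares the reference unit so variants are comparable
    nor2$units <- lapply(seq_len(spec2$n_units), function(u)
      mutate_unit(nor$reference_unit, unit_annotation(spec2),
                  spec2$variant_rate, indel_fraction = spec2$indel_fraction,
                  indel_mean = spec2$indel_mean, indel_max = spec2$indel_max,
                  seed = seeds[4] + u)$sequence)
    u2 <- setNames(nor2$units, paste0("chr21_unit", seq_along(nor2$units)))
    units <- c(units, u2)
    groups <- c(groups, setNames(rep("chr21", length(u2)), names(u2)))
  }
  uann <- unit_annotation(spec)
  align_args <- list(match = config$variants$match,
                     mismatch = config$variants$mismatch,
                     gap_open = config$variants$gap_open,
                     gap_extend = config$variants$gap_extend,
                     band = config$variants$band)
  calls <- lapply(units, function(u)
    call_variants(do.call(align_units,
                          c(list(nor$reference_unit, u), align_args)), uann))
  all_calls <- do.call(rbind, lapply(names(calls), function(nm) {
    df <- calls[[nm]]
    if (nrow(df)) df$unit <- nm
    df
  }))
  write_variants(data.frame(unit = all_calls$unit, pos = all_calls$pos,
                            ref = all_calls$ref, alt = all_calls$alt,
                            type = all_calls$type, region = all_calls$region),
                 file.path(out_dir, "called_variants.tsv"))
  div <- do.call(pairwise_divergence, c(list(units, groups), align_args))
  shr <- classify_sharing(lapply(calls, variant_key), groups)
  dens <- region_density(do.call(rbind, calls[groups == "chr22"]), uann)
  report$variants <- list(
    per_unit_counts = vapply(calls, nrow, integer(1)),
    divergence = div$summary,
    sharing = as.list(table(shr$class)),
    igs_to_transcribed = dens$igs_to_transcribed)

  # 6. RNA structure impact of the first transcribed-region variant
  tx_regions <- setdiff(NOR_REGIONS, "IGS")
  cand <- all_calls[all_calls$region %in% tx_regions & all_calls$type == "SNV", ]
  if (nrow(cand)) {
    v <- as.list(cand[1, c("pos", "type", "ref", "alt")])
    fp <- fold_params(model = config$structure$model,
                      windows = config$structure$windows)
    w <- max(config$structure$windows)
    ws <- max(1L, v$pos - w %/% 2L)
    ref_win <- substr(nor$reference_unit, ws, min(nchar(nor$reference_unit),
                                                  ws + w - 1L))
    v_local <- v; v_local$pos <- v$pos - ws + 1L
    alt_win <- apply_variant(ref_win, v_local)
    imp <- call_ribosnitch(ref_win, alt_win, fp,
                           alpha = config$structure$alpha,
                           n_rand = config$structure$n_rand, seed = seeds[5])
    report$structure <- list(variant = v, ribosnitch = imp$ribosnitch,
                             windows = imp$windows)
  } else {
    report$structure <- list(variant = NULL, ribosnitch = NA)
  }

  # 7. copy number
  copies <- c(calibrator = config$qpcr$calibrator_copies,
              sample22 = config$qpcr$copies)
  ct <- simulate_qpcr(copies, calibrator = "calibrator",
                      n_amplicons = config$qpcr$n_amplicons,
                      n_replicates = config$qpcr$n_replicates,
                      efficiency = config$qpcr$efficiency,
                      noise_sd = config$qpcr$noise_sd, seed = seeds[6])
  est <- estimate_copies(ct, "calibrator", config$qpcr$calibrator_copies)
  write.table(ct, file.path(out_dir, "qpcr_ct.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report$copy_number <- list(true_copies = config$qpcr$copies,
                             estimate = est$copies[est$sample == "sample22"],
                             se = est$se[est$sample == "sample22"])

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns")
  invisible(report)
}
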