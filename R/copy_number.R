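# Relative qPCR copy-number estimation for rDNA repeats.
#
# Targets are IGS amplicons; the control is a single-copy locus (e.g. the
# chromosome 22 PMM1 region).  Quantities are relative to a calibrator sample
# of known (user-supplied) copy number; with per-amplicon efficiency E the
# relative quantity is (1+E_t)^(-dCt_t) / (1+E_c)^(-dCt_c).

#' Simulate a qPCR Ct table from known copy numbers
#'
#' Inverse of the estimation model: Ct = Ct0 - log_{1+E}(copies) + noise,
#' with the control locus at 2 copies (single-copy diploid) in every sample.
#'
#' @param copies Named numeric vector of true rDNA copy numbers per sample
#'   (include the calibrator).
#' @param calibrator Name of the calibrator sample.
#' @param n_amplicons Number of IGS target amplicons (default 4, named after
#'   IGS primer positions).
#' @param n_replicates Technical replicates per amplicon (default 3).
#' @param efficiency Amplification efficiency in (0, 1] (default 1).
#' @param noise_sd Gaussian Ct noise (cycles, default 0.2).
#' @param seed Optional integer seed.
#' @return Data frame `sample`, `amplicon`, `type`, `replicate`, `ct` with an
#'   `efficiencies` attribute.
#' @export
simulate_qpcr <- function(copies, calibrator = names(copies)[1],
                          n_amplicons = 4L, n_replicates = 3L,
                          efficiency = 1, noise_sd = 0.2, seed = NULL) {
  stopifnot(!is.null(names(copies)), calibrator %in% names(copies),
            efficiency > 0, efficiency <= 1)
  with_seed(seed, {
    amps <- paste0("IGS_", c(122992L, 129514L, 134304L, 142197L,
                             round(runif(max(0, n_amplicons - 4)) * 3e4) + 110000L)[
                               seq_len(n_amplicons)])
    ct0 <- setNames(runif(n_amplicons + 1, 18, 24), c(amps, "PMM1"))
    rows <- list()
    for (s in names(copies)) {
      for (a in amps) {
        ct <- ct0[[a]] - log(copies[[s]]) / log(1 + efficiency) +
          rnorm(n_replicates, 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, amplicon = a, type = "target",
          replicate = seq_len(n_replicates), ct = ct)
      }
      ctc <- ct0[["PMM1"]] - log(2) / log(1 + efficiency) +
        rnorm(n_replicates, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, amplicon = "PMM1", type = "control",
        replicate = seq_len(n_replicates), ct = ctc)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "efficiencies") <- setNames(rep(efficiency, n_amplicons + 1),
                                          c(amps, "PMM1"))
    out
  })
}

#' Estimate rDNA copy number from a qPCR Ct table
#'
#' Relative quantification against a single-copy control and a calibrator
#' sample of known copy number.  Per amplicon and replicate,
#' `q = (1+E_t)^-(Ct_t - Ct_t,cal) / (1+E_c)^-(Ct_c - Ct_c,cal) * calibrator_copies`;
#' the per-sample estimate is the mean over IGS amplicons with the SE taken
#' over all amplicon x replicate quantities.
#'
#' @param table Ct data frame (`sample`, `amplicon`, `type`, `replicate`,
#'   `ct`) as from [simulate_qpcr()] or [read_ct_table()].
#' @param calibrator Calibrator sample id.
#' @param calibrator_copies Known copy number of the calibrator (required;
#'   the implied "total genomic DNA" value is study-specific, not a
#'   constant).
#' @param efficiencies Named per-amplicon efficiencies in (0, 1]; default 1
#'   for all (perfect doubling).
#' @return Data frame `sample`, `copies`, `se`, `n_measurements`.
#' @export
estimate_copies <- function(table, calibrator, calibrator_copies,
                            efficiencies = NULL) {
  need <- c("sample", "amplicon", "type", "replicate", "ct")
  stopifnot(all(need %in% names(table)))
  if (any(table$ct <= 0)) stop("all Ct values must be > 0")
  if (!calibrator %in% table$sample) stop("calibrator sample missing")
  samples <- unique(table$sample)
  for (s in samples)
    if (!any(table$sample == s & table$type == "control"))
      stop("missing control rows for sample ", s)
  amps <- unique(table$amplicon[table$type == "target"])
  ctrl_amp <- unique(table$amplicon[table$type == "control"])
  if (length(ctrl_amp) != 1) stop("expected exactly one control amplicon")
  if (is.null(efficiencies)) {
    if (!is.null(attr(table, "efficiencies")))
      efficiencies <- attr(table, "efficiencies")
    else efficiencies <- setNames(rep(1, length(amps) + 1), c(amps, ctrl_amp))
  }
  if (any(efficiencies <= 0 | efficiencies > 1))
    stop("efficiencies must lie in (0, 1]")
  mean_ct <- function(s, a)
    mean(table$ct[table$sample == s & table$amplicon == a])
  e_c <- efficiencies[[ctrl_amp]]
  rows <- lapply(samples, function(s) {
    dctc <- mean_ct(s, ctrl_amp) - mean_ct(calibrator, ctrl_amp)
    q <- unlist(lapply(amps, function(a) {
      e_t <- efficiencies[[a]]
      cal_ct <- mean_ct(calibrator, a)
      cts <- table$ct[table$sample == s & table$amplicon == a]
      (1 + e_t)^(-(cts - cal_ct)) / (1 + e_c)^(-dctc) * calibrator_copies
    }))
    per_amp <- vapply(amps, function(a) {
      e_t <- efficiencies[[a]]
      (1 + e_t)^(-(mean_ct(s, a) - mean_ct(calibrator, a))) /
        (1 + e_c)^(-dctc) * calibrator_copies
    }, numeric(1))
    data.frame(sample = s, copies = mean(per_amp), se = sem(q),
               n_measurements = length(q), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
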