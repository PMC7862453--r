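zero_rates <- setNames(rep(0, 8), norkit:::NOR_REGIONS)

test_that("zero variant rates give byte-identical units and exact lengths", {
  spec <- nor_spec(n_units = 2, scale = 0.05, variant_rate = zero_rates,
                   seed = 3)
  nor <- build_nor(spec)
  expect_identical(nor$units[[1]], nor$units[[2]])
  expect_identical(nor$units[[1]], nor$reference_unit)
  expect_equal(nrow(nor$truth_variants), 0)
  expect_equal(nchar(nor$sequence),
               spec$pj_length + 2 * sum(spec$region_lengths) + spec$dj_length)
})

test_that("annotation tiles the sequence and truth variants sit in their regions", {
  spec <- nor_spec(n_units = 3, scale = 0.1, seed = 9)
  nor <- build_nor(spec)
  ann <- nor$annotation
  expect_equal(ann$start[1], 1L)
  expect_equal(ann$end[nrow(ann)], nchar(nor$sequence))
  expect_true(all(ann$start[-1] == head(ann$end, -1) + 1L))
  # conservation: region lengths sum to the sequence length
  expect_equal(sum(ann$end - ann$start + 1), nchar(nor$sequence))
  # every truth variant lies inside its annotated region (reference coords)
  uann <- norkit:::unit_annotation(spec)
  tv <- nor$truth_variants
  for (i in seq_len(nrow(tv))) {
    reg <- uann[uann$region == tv$region[i], ]
    expect_gte(tv$pos[i], reg$start - 1L)  # left-aligned INS may anchor at start-1
    expect_lte(tv$pos[i], reg$end)
  }
})

test_that("identical (spec, seed) reproduces the instance byte-for-byte", {
  spec <- nor_spec(n_units = 2, scale = 0.05, seed = 77)
  a <- build_nor(spec)
  b <- build_nor(spec)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$truth_variants, b$truth_variants)
})

test_that("truth records reconstruct each mutated unit exactly", {
  spec <- nor_spec(n_units = 3, scale = 0.1, seed = 21)
  nor <- build_nor(spec)
  for (u in seq_len(spec$n_units)) {
    tv <- nor$truth_variants[nor$truth_variants$unit == u, , drop = FALSE]
    expect_identical(apply_truth_variants(nor$reference_unit, tv),
                     nor$units[[u]])
  }
})

test_that("truth variant counts follow the Poisson expectation", {
  rates <- setNames(rep(7.5, 8), norkit:::NOR_REGIONS)
  rates[["IGS"]] <- 15
  spec <- nor_spec(n_units = 4, scale = 0.1, variant_rate = rates, seed = 13)
  nor <- build_nor(spec)
  lens <- spec$region_lengths
  lambda <- spec$n_units *
    sum(rates[norkit:::NOR_REGIONS] * lens[norkit:::NOR_REGIONS] / 1000)
  n_obs <- nrow(nor$truth_variants)
  expect_lt(abs(n_obs - lambda), 3 * sqrt(lambda))
})

test_that("planted enzyme sites appear in the flanks and never in the array", {
  spec <- nor_spec(n_units = 2, scale = 0.1, seed = 5)
  nor <- build_nor(spec)
  arr <- norkit:::array_interval(nor)
  for (enz in names(spec$planted_sites)) {
    sm <- scan_sites(nor$sequence, enz)
    expect_true(all(nor$planted_site_positions[[enz]] %in% sm$positions))
    inside <- sm$positions[sm$positions >= arr[1] & sm$positions <= arr[2]]
    expect_length(inside, 0)
    array_scan <- scan_sites(subseq_chr(nor$sequence, arr[1], arr[2]), enz)
    expect_length(array_scan$positions, 0)
  }
})

test_that("mutate_unit handles trivial and degenerate cases", {
  ref <- random_dna(2000, 0.5)
  ann <- data.frame(region = c("18S", "IGS"), start = c(1L, 1001L),
                    end = c(1000L, 2000L))
  r0 <- mutate_unit(ref, ann, c("18S" = 0, IGS = 0), seed = 1)
  expect_identical(r0$sequence, ref)
  expect_equal(nrow(r0$variants), 0)

  expect_error(mutate_unit(ref, ann, c("18S" = 1), seed = 1), "IGS")
  ann0 <- data.frame(region = "18S", start = 1L, end = 0L)
  expect_error(mutate_unit("", ann0, c("18S" = 5), seed = 1), "zero length")
})

test_that("single-SNV bookkeeping records position and alleles faithfully", {
  ref <- random_dna(500, 0.5)
  ann <- data.frame(region = "18S", start = 1L, end = 500L)
  found <- FALSE
  for (s in 1:50) {
    r <- mutate_unit(ref, ann, c("18S" = 2), indel_fraction = 0, seed = s)
    if (nrow(r$variants) == 1) {
      v <- r$variants
      expect_equal(v$type, "SNV")
      expect_identical(substr(ref, v$pos, v$pos), v$ref)
      expect_identical(substr(r$sequence, v$pos, v$pos), v$alt)
      diff_at <- which(strsplit(ref, "")[[1]] != strsplit(r$sequence, "")[[1]])
      expect_equal(diff_at, v$pos)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("empirical mutation rate matches the requested rate within 5%", {
  ref <- random_dna(1000, 0.5)
  ann <- data.frame(region = "IGS", start = 1L, end = 1000L)
  counts <- with_seed(42, vapply(1:1000, function(i)
    nrow(mutate_unit(ref, ann, c(IGS = 7.5))$variants), numeric(1)))
  expect_lt(abs(mean(counts) - 7.5) / 7.5, 0.05)
})

test_that("per-region rates are recovered over many simulated units", {
  spec <- nor_spec(scale = 0.1, seed = 1)
  uann <- norkit:::unit_annotation(spec)
  rates <- spec$variant_rate
  n_rep <- 500
  counts <- setNames(numeric(length(norkit:::NOR_REGIONS)),
                     norkit:::NOR_REGIONS)
  with_seed(7, for (i in seq_len(n_rep)) {
    v <- mutate_unit(random_dna(sum(spec$region_lengths), 0.5), uann, rates,
                     indel_fraction = spec$indel_fraction)$variants
    tab <- table(v$region)
    counts[names(tab)] <- counts[names(tab)] + tab
  })
  for (reg in norkit:::NOR_REGIONS) {
    len <- uann$end[uann$region == reg] - uann$start[uann$region == reg] + 1
    lambda <- n_rep * rates[[reg]] * len / 1000
    if (lambda == 0) {
      expect_equal(unname(counts[reg]), 0)
    } else {
      # 5% or 3 SD, whichever is looser (binomial tolerance at small lambda)
      tol <- max(0.05 * lambda, 3 * sqrt(lambda))
      expect_lt(abs(counts[[reg]] - lambda), tol)
    }
  }
})

test_that("simulate_clone emits vector+insert at rotation 0 and errors on in-array cuts", {
  spec <- nor_spec(n_units = 2, scale = 0.05, variant_rate = zero_rates,
                   seed = 8)
  nor <- build_nor(spec)
  vec <- with_seed(2, random_dna(400, 0.5))
  cl <- simulate_clone(nor, "EcoRV", vector_seq = vec, rotation = 0,
                       circular_overlap = 0, seed = 3)
  expect_identical(cl$emission, paste0(vec, cl$insert))
  expect_identical(cl$insert,
                   subseq_chr(nor$sequence, cl$fragment$start, cl$fragment$end))

  # an enzyme whose motif occurs mid-array must be refused, naming a position
  mid <- substr(nor$units[[1]], 501, 506)
  expect_error(simulate_clone(nor, list(name = "BadEnz", motif = mid)),
               "position [0-9]+")
})

test_that("nor export files parse back with the package readers", {
  spec <- nor_spec(n_units = 2, scale = 0.05, seed = 12)
  nor <- build_nor(spec)
  dir <- withr::local_tempdir()
  paths <- write_nor(nor, dir, "toy")
  fa <- read_fasta(paths[["fasta"]])
  expect_identical(unname(fa), nor$sequence)
  bed <- read_bed(paths[["bed"]])
  expect_equal(bed$start, nor$annotation$start)
  tv <- read_variants(paths[["variants"]])
  expect_equal(nrow(tv), nrow(nor$truth_variants))
})
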