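test_that("circular overlap trimming matches the brute-force oracle", {
  # 3-symbol terminal repeat, min_overlap 3
  s <- "GATTACAGAT"
  r <- trim_circular_overlap(s, min_overlap = 3, max_divergence = 0)
  expect_equal(r$removed, 3)
  expect_identical(r$sequence, "GATTACA")
  # idempotent
  r2 <- trim_circular_overlap(r$sequence, min_overlap = 3, max_divergence = 0)
  expect_equal(r2$removed, 0)

  # no terminal repeat -> unchanged
  expect_equal(trim_circular_overlap("ACGTACGGTT", 3, 0)$removed, 0)

  # whole-sequence self-identity is never an overlap (overlap < len/2)
  expect_equal(trim_circular_overlap("ACGACG", 3, 0)$removed, 0)

  with_seed(30, {
    for (i in 1:50) {
      core <- random_dna(sample(300:800, 1), 0.5)
      ov <- sample(c(0, 3:120), 1)
      s <- paste0(core, substr(core, 1, ov))
      truth <- oracle_terminal_overlap(s, 3, 0)
      got <- trim_circular_overlap(s, min_overlap = 3, max_divergence = 0)
      expect_equal(got$removed, truth)
    }
  })
})

test_that("finishing handles linear input with the vector at position 1", {
  with_seed(6, {
    vec <- random_dna(300, 0.5)
    ins <- random_dna(1200, 0.5)
    fin <- finish_assembly(paste0(vec, ins), vec, min_overlap = 50)
    expect_identical(fin$insert, ins)
    expect_equal(fin$reoriented_offset, 0)
    expect_equal(fin$circular_overlap_removed, 0)
  })
})

test_that("finishing errors when the vector is absent and flags missing hooks", {
  with_seed(61, {
    vec <- random_dna(300, 0.5)
    ins <- random_dna(1000, 0.5)
    expect_error(finish_assembly(ins, vec), "vector absent")
    fin <- finish_assembly(paste0(vec, ins), vec,
                           hooks = c(good = substr(ins, 1, 60),
                                     missing = random_dna(60, 0.5)))
    expect_true(fin$hooks_found[["good"]])
    expect_false(fin$hooks_found[["missing"]])
    expect_false(fin$valid)
  })
})

test_that("finishing recovers the truth insert for rotated, overlapped clones", {
  spec <- nor_spec(n_units = 2, scale = 0.05, seed = 2)
  nor <- build_nor(spec)
  with_seed(15, {
    for (i in 1:30) {
      cl <- simulate_clone(nor, sample(c("EcoRV", "ApaLI"), 1),
                           rotation = sample.int(6000, 1) - 1L,
                           circular_overlap = sample(c(0, 100:500), 1),
                           seed = sample.int(1e6, 1))
      fin <- finish_assembly(cl$emission, cl$vector,
                             hooks = c(h5 = cl$hook5, h3 = cl$hook3))
      expect_identical(fin$insert, cl$insert)
      expect_equal(fin$circular_overlap_removed, cl$circular_overlap)
      expect_true(fin$valid)
    }
  })
})

test_that("finishing tolerates a diverged vector copy and flipped strand", {
  with_seed(91, {
    vec <- random_dna(600, 0.5)
    ins <- random_dna(3000, 0.5)
    noisy_vec <- vec
    for (p in sample(600, 12)) {  # 2% mismatch
      b <- substr(noisy_vec, p, p)
      substr(noisy_vec, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }
    asm <- rotate_seq(paste0(noisy_vec, ins), 700)
    fin <- finish_assembly(asm, vec, min_overlap = 50)
    expect_equal(nchar(fin$insert), 3000)
    expect_gt(sum(strsplit(fin$insert, "")[[1]] ==
                  strsplit(ins, "")[[1]]) / 3000, 0.99)
    # reverse-complemented assembly: vector found on the minus strand
    fin2 <- finish_assembly(revcomp(paste0(vec, ins)), vec, min_overlap = 50)
    expect_identical(fin2$insert, ins)
    expect_equal(fin2$strand, "-")
  })
})

test_that("merge_inserts matches spec arithmetic, brute force, and guards", {
  m <- merge_inserts("ACGTACGT", "ACGTTTTT", min_overlap = 4,
                     max_mismatch_rate = 0)
  expect_equal(nchar(m$contig), 12)
  expect_equal(m$overlap_length, 4)
  expect_identical(m$contig, "ACGTACGTTTTT")

  a <- with_seed(3, random_dna(500, 0.5))
  expect_error(merge_inserts(a, a, min_overlap = 10), "no qualifying overlap")

  with_seed(44, {
    for (i in 1:25) {
      x <- random_dna(sample(400:900, 1), 0.5)
      y_tail <- random_dna(sample(200:600, 1), 0.5)
      ov <- sample(60:200, 1)
      y <- paste0(substr(x, nchar(x) - ov + 1, nchar(x)), y_tail)
      flip <- runif(1) < 0.5
      swap <- runif(1) < 0.5
      b <- if (flip) revcomp(y) else y
      m <- if (swap) merge_inserts(b, x, min_overlap = 50, ids = c("B", "A"))
           else merge_inserts(x, b, min_overlap = 50)
      truth <- oracle_suffix_prefix(x, y, 50, 0.01)
      expect_equal(m$overlap_length, truth$overlap)
      expect_equal(nchar(m$contig), nchar(x) + nchar(y) - truth$overlap)
      # the contig may be reported on either strand depending on input order
      expect_true(m$contig %in% c(paste0(x, y_tail), revcomp(paste0(x, y_tail))))
      expect_equal(m$strand, if (flip) "-" else "+")
    }
  })
})

test_that("sub-threshold overlaps are reported in the merge error", {
  with_seed(55, {
    x <- random_dna(400, 0.5)
    ov_seq <- substr(x, 301, 400)
    noisy <- ov_seq
    for (p in seq(40, 90, by = 10))
      substr(noisy, p, p) <- setdiff(c("A", "C", "G", "T"),
                                     substr(noisy, p, p))[1]
    y <- paste0(noisy, random_dna(200, 0.5))
    expect_error(merge_inserts(x, y, min_overlap = 50,
                               max_mismatch_rate = 0.001),
                 "sub-threshold candidate")
  })
})

test_that("a PJ clone and an array clone merge into the exact NOR slice", {
  spec <- nor_spec(n_units = 2, scale = 0.1, seed = 23)
  nor <- build_nor(spec)
  frag <- nor$truth_fragments[["EcoRV"]]
  overlap_len <- 800L
  pj_clone <- subseq_chr(nor$sequence, 1, frag$start + overlap_len - 1L)
  cl <- simulate_clone(nor, "EcoRV", seed = 5)
  fin <- finish_assembly(cl$emission, cl$vector)
  m <- merge_inserts(pj_clone, fin$insert, min_overlap = 100,
                     ids = c("PJ", "EcoRV_clone"))
  expect_equal(m$overlap_length, overlap_len)
  expect_identical(m$contig, subseq_chr(nor$sequence, 1, frag$end))
  expect_equal(nchar(m$contig),
               nchar(pj_clone) + nchar(fin$insert) - m$overlap_length)
})
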