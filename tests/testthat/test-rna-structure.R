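test_that("folding handles canonical small cases", {
  s <- fold("GGGAAAACCC")
  expect_equal(nrow(s$pairs), 3)
  expect_equal(s$score, 3)
  expect_equal(fold("AAAAAAAAAA")$score, 0)
  expect_equal(nrow(fold("AAAAAAAAAA")$pairs), 0)
  # too short to pair: trivial all-unpaired structure
  short <- fold("GC")
  expect_equal(nrow(short$pairs), 0)
  # T is read as U
  expect_equal(fold("GGGAAAACCC")$score, fold("GGGTTTTCCC", )$score + 3 - 3)
})

test_that("structures are valid: non-crossing, min-loop, partner-consistent", {
  with_seed(12, {
    for (i in 1:40) {
      s <- random_rna(sample(10:60, 1))
      st <- fold(s)
      p <- st$partner
      idx <- which(p > 0)
      expect_true(all(p[p[idx]] == idx))        # involution
      if (nrow(st$pairs)) {
        expect_true(all(st$pairs[, 2] - st$pairs[, 1] > 3))  # min_loop
        # non-crossing
        for (r in seq_len(nrow(st$pairs))) {
          i1 <- st$pairs[r, 1]; j1 <- st$pairs[r, 2]
          inside <- st$pairs[, 1] > i1 & st$pairs[, 1] < j1
          expect_true(all(st$pairs[inside, 2] < j1))
        }
      }
      # dot-bracket rendering round-trips
      rt <- parse_dot_bracket(dot_bracket(st))
      expect_equal(rt$partner, st$partner)
    }
  })
})

test_that("both DP models equal exhaustive enumeration on short sequences", {
  with_seed(99, {
    for (i in 1:60) {
      s <- random_rna(sample(6:16, 1))
      for (model in c("pairmax", "stacks")) {
        got <- fold(s, fold_params(model = model))$score
        expect_equal(got, oracle_best_fold(s, model),
                     info = paste(model, s))
      }
    }
  })
})

test_that("opening penalties are non-negative and match constrained brute force", {
  # interval already unpaired in the optimum -> 0
  op <- opening_penalty("GGGAAAACCCAAAA", c(12, 14))
  expect_equal(op$delta_g_open, 0)
  # breaking a hairpin stem costs its pairs under pair maximization
  op2 <- opening_penalty("GGGGAAAACCCC", c(1, 4))
  expect_equal(op2$delta_g_open, 4)
  expect_error(opening_penalty("GGGAAAACCC", c(5, 200)), "interval")

  with_seed(7, {
    for (i in 1:30) {
      s <- random_rna(sample(8:15, 1))
      n <- nchar(s)
      iv <- sort(sample.int(n, 2))
      for (model in c("pairmax", "stacks")) {
        fp <- fold_params(model = model)
        got <- opening_penalty(s, iv, fp)$delta_g_open
        oracle <- oracle_best_fold(s, model) -
          oracle_best_fold(s, model, unpaired = iv[1]:iv[2])
        expect_gte(got, 0)
        expect_equal(got, oracle, info = paste(model, s))
      }
    }
  })
})

test_that("opening penalty is monotone under interval inclusion", {
  with_seed(70, {
    for (i in 1:20) {
      s <- random_rna(sample(20:50, 1))
      n <- nchar(s)
      st <- sample.int(n - 4, 1)
      small <- c(st, st + 1)
      big <- c(max(1, st - 2), min(n, st + 4))
      expect_gte(opening_penalty(s, big)$delta_g_open,
                 opening_penalty(s, small)$delta_g_open)
    }
  })
})

test_that("structural index D is the indicator-vector norm and a metric", {
  s1 <- parse_dot_bracket("(((...)))...")
  expect_equal(structural_index(s1, s1), 0)
  expect_equal(structural_index(parse_dot_bracket("((((...))))"),
                                parse_dot_bracket(".(((...))).")), 1)

  with_seed(41, {
    rand_struct <- function(n) {
      s <- random_rna(n)
      mask <- sample.int(n, sample(0:(n %/% 2), 1))
      fold(s, unpaired = if (length(mask)) mask else NULL)
    }
    for (i in 1:40) {
      n <- sample(15:40, 1)
      a <- rand_struct(n); b <- rand_struct(n); c_ <- rand_struct(n)
      # oracle: symmetric difference of pair sets, counted directly
      sym <- function(x, y) {
        kx <- apply(x$pairs, 1, paste, collapse = "-")
        ky <- apply(y$pairs, 1, paste, collapse = "-")
        if (!nrow(x$pairs)) kx <- character(0)
        if (!nrow(y$pairs)) ky <- character(0)
        sqrt(sum(!kx %in% ky) + sum(!ky %in% kx))
      }
      dab <- structural_index(a, b)
      expect_equal(dab, sym(a, b))
      expect_equal(dab, structural_index(b, a))          # symmetry
      expect_equal(structural_index(a, a), 0)            # identity
      expect_lte(dab, structural_index(a, c_) + structural_index(c_, b) + 1e-9)
    }
  })
  expect_error(structural_index(parse_dot_bracket("..."),
                                parse_dot_bracket("....")), "map")
})

test_that("indel alleles are compared through the coordinate map", {
  ref <- "GGGGAAAACCCCAAAAA"
  v <- list(pos = 12L, type = "INS", ref = "", alt = "GG")
  alt <- apply_variant(ref, v)
  m <- norkit:::variant_coordinate_map(nchar(ref), nchar(alt), v)
  expect_equal(length(m), nchar(alt))
  expect_true(all(is.na(m[13:14])))
  expect_equal(m[15], 13)
  d <- structural_index(fold(ref), fold(alt), map = m)
  expect_gte(d, 0)
})

test_that("randomization nulls behave at the boundaries and are reproducible", {
  with_seed(8, {
    s <- random_rna(60)
    # variant whose alternate equals the reference: observed 0, p = 1
    v_null <- list(pos = 10L, type = "SNV", ref = substr(s, 10, 10),
                   alt = substr(s, 10, 10))
    rn <- randomization_null(s, v_null, n = 25, seed = 5)
    expect_equal(rn$observed, 0)
    expect_equal(rn$empirical_p, 1)

    v <- list(pos = 30L, type = "SNV", ref = substr(s, 30, 30), alt = "G")
    a <- randomization_null(s, v, n = 30, seed = 42)
    b <- randomization_null(s, v, n = 30, seed = 42)
    expect_identical(a$null, b$null)
    expect_equal(a$empirical_p, b$empirical_p)
    expect_gte(a$empirical_p, 1 / 31)
    expect_lte(a$empirical_p, 1)
  })
  expect_error(randomization_null("ACGU", list(), n = 5), ">= 20")
})

test_that("empirical P-values are valid (super-uniform) under the null", {
  # the statistic is discrete, so p has atoms and is conservative rather
  # than exactly uniform; validity P(p <= t) <= t is the guaranteed property
  with_seed(29, {
    fp <- fold_params("stacks")
    n_rand <- 24
    ps <- vapply(1:120, function(i) {
      s <- random_rna(60)
      pos <- sample(5:55, 1)
      alt <- sample(setdiff(c("A", "C", "G", "U"), substr(s, pos, pos)), 1)
      v <- list(pos = pos, type = "SNV", ref = substr(s, pos, pos), alt = alt)
      randomization_null(s, v, fp, n = n_rand,
                         seed = sample.int(1e6, 1))$empirical_p
    }, numeric(1))
    expect_true(all(ps >= 1 / (n_rand + 1)))
    expect_true(all(ps <= 1))
    for (t in c(0.05, 0.1, 0.25, 0.5, 0.75)) {
      slack <- 3 * sqrt(t * (1 - t) / length(ps))
      expect_lte(mean(ps <= t), t + slack)
    }
  })
})

test_that("shuffles preserve the advertised composition", {
  with_seed(33, {
    s <- random_rna(80)
    mono <- shuffle_seq(s, "mono")
    expect_equal(sort(strsplit(mono, "")[[1]]), sort(strsplit(s, "")[[1]]))
    di <- shuffle_seq(s, "dinucleotide")
    count_di <- function(x) {
      ch <- strsplit(x, "")[[1]]
      table(paste0(head(ch, -1), ch[-1]))
    }
    expect_equal(count_di(di), count_di(s))
  })
})

test_that("MWW exact enumeration, approximation, and degenerate ties agree", {
  r <- mww_test(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3)
  expect_equal(r$method, "exact")

  x <- c(5, 6, 7)
  expect_equal(mww_test(x, x)$p, 1)
  expect_equal(mww_test(c(1, 1), c(1, 1))$p, 1)

  # exact result matches stats::wilcox.test where both are exact (no ties)
  with_seed(61, {
    for (i in 1:20) {
      x <- sample(100, 5); y <- sample(200, 6)
      while (any(x %in% y)) y <- sample(200, 6)
      ours <- mww_test(x, y)
      ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
      expect_equal(ours$U, unname(ref$statistic))
      expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    }
  })

  # normal approximation close to exact at n = 12
  with_seed(62, {
    devs <- vapply(1:100, function(i) {
      x <- stats::runif(6); y <- stats::runif(6) + stats::runif(1, -0.5, 0.5)
      abs(mww_test(x, y, exact_max = 12)$p - mww_test(x, y, exact_max = 0)$p)
    }, numeric(1))
    expect_lt(stats::median(devs), 0.05)
    expect_lt(mean(devs), 0.06)
  })
})

test_that("riboSNitch calls separate designed positive and negative controls", {
  stem <- 14
  hp <- paste0(strrep("G", stem), "AAAA", strrep("C", stem))
  s <- paste0(strrep("A", 34), hp, strrep("A", 34))  # only the stem can pair
  alt <- s
  substr(alt, 41, 41) <- "A"  # break the middle of the 5' stem arm
  fp <- fold_params(model = "stacks", windows = 100L)
  pos <- call_ribosnitch(s, alt, fp, n_rand = 100, seed = 7)
  expect_true(pos$ribosnitch)
  expect_lte(pos$windows$empirical_p[1], 0.05)
  expect_gt(pos$windows$D[1], 0)

  # composition-preserving SNV in an unstructured poly-purine context
  with_seed(19, {
    neg_ref <- paste(sample(c("A", "G"), 100, TRUE), collapse = "")
    neg_alt <- neg_ref
    substr(neg_alt, 50, 50) <- if (substr(neg_ref, 50, 50) == "A") "G" else "A"
    neg <- call_ribosnitch(neg_ref, neg_alt, fp, n_rand = 100, seed = 8)
    expect_false(neg$ribosnitch)
    expect_equal(neg$windows$D[1], 0)
  })

  same <- call_ribosnitch(s, s, fp)
  expect_false(same$ribosnitch)
  expect_equal(same$windows$D[1], 0)
})
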