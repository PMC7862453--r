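test_that("identical sequences align with zero edits and full consumption", {
  s <- with_seed(2, random_dna(1000, 0.5))
  p <- align_units(s, s)
  expect_true(all(p$ops == 0L))
  expect_equal(nrow(call_variants(p)), 0)
})

test_that("planted SNVs and a deletion are recovered exactly", {
  with_seed(17, {
    a <- random_dna(300, 0.5)
    b <- a
    substr(b, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(a, 50, 50))[1]
    substr(b, 170, 170) <- setdiff(c("A", "C", "G", "T"), substr(a, 170, 170))[1]
    b <- paste0(substr(b, 1, 219), substr(b, 223, 300))  # 3 bp deletion
    v <- call_variants(align_units(a, b))
    expect_equal(nrow(v), 3)
    expect_equal(v$type, c("SNV", "SNV", "DEL"))
    expect_equal(v$pos[1:2], c(50, 170))
    expect_equal(nchar(v$ref[3]), 3)
    # deletion reported at its leftmost equivalent placement
    del <- v[3, ]
    expect_false(del$pos > 1 &&
                 substr(a, del$pos - 1, del$pos - 1) ==
                 substr(a, del$pos + 2, del$pos + 2))
  })
})

test_that("banded alignment scores equal an independent global aligner", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  with_seed(23, {
    for (i in 1:50) {
      n <- sample(200:2000, 1)
      a <- random_dna(n, 0.5)
      ann <- data.frame(region = "IGS", start = 1L, end = n)
      b <- mutate_unit(a, ann, c(IGS = sample(c(5, 10, 20), 1)))$sequence
      banded <- align_units(a, b)
      ref <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 1,
        scoreOnly = TRUE)
      expect_equal(banded$score, ref)
    }
  })
})

test_that("homopolymer deletions are reported at the leftmost placement", {
  a <- "AACCCCCAATT"
  b <- "AACCCCAATT"  # one C of the run deleted
  v <- call_variants(align_units(a, b))
  expect_equal(nrow(v), 1)
  expect_equal(v$type, "DEL")
  expect_equal(v$pos, 3)  # leftmost C of the run
  # enumeration of equivalent placements confirms 3 is the minimum
  equiv <- Filter(function(p) {
    paste0(substr(a, 1, p - 1), substr(a, p + 1, nchar(a))) == b
  }, 1:nchar(a))
  expect_equal(v$pos, min(equiv))
})

test_that("region labels follow the annotation and unannotated is kept", {
  ann <- data.frame(region = c("18S", "IGS"), start = c(1L, 101L),
                    end = c(100L, 200L))
  with_seed(5, {
    a <- random_dna(250, 0.5)
    b <- a
    for (p in c(50, 150, 230))
      substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), substr(a, p, p))[1]
    v <- call_variants(align_units(a, b), ann)
    expect_equal(v$region, c("18S", "IGS", "unannotated"))
  })
})

test_that("variant calling recovers simulation truth with high fidelity", {
  spec <- nor_spec(scale = 0.1, seed = 3)
  uann <- norkit:::unit_annotation(spec)
  ref <- with_seed(10, random_dna(sum(spec$region_lengths), 0.55))
  tp <- fp <- fn <- 0
  with_seed(67, {
    for (i in 1:20) {
      mu <- mutate_unit(ref, uann, spec$variant_rate * 5)
      called <- call_variants(align_units(ref, mu$sequence), uann)
      truth_keys <- variant_key(mu$variants)
      called_keys <- variant_key(called)
      tp <- tp + length(intersect(truth_keys, called_keys))
      fp <- fp + length(setdiff(called_keys, truth_keys))
      fn <- fn + length(setdiff(truth_keys, called_keys))
    }
  })
  expect_gt(tp / (tp + fp), 0.95)  # precision
  expect_gt(tp / (tp + fn), 0.95)  # recall
})

test_that("variant counts are symmetric in the input order", {
  with_seed(31, {
    for (i in 1:10) {
      a <- random_dna(800, 0.5)
      ann <- data.frame(region = "IGS", start = 1L, end = 800L)
      b <- mutate_unit(a, ann, c(IGS = 10))$sequence
      expect_equal(nrow(call_variants(align_units(a, b))),
                   nrow(call_variants(align_units(b, a))))
    }
  })
})

test_that("pairwise divergence summarises counts with the closed-form SEM", {
  s <- with_seed(40, random_dna(600, 0.5))
  # construct units with deterministic pair counts {1, 2, 3}
  b <- s; substr(b, 100, 100) <- setdiff(c("A","C","G","T"), substr(s,100,100))[1]
  c_ <- s
  substr(c_, 300, 300) <- setdiff(c("A","C","G","T"), substr(s,300,300))[1]
  substr(c_, 400, 400) <- setdiff(c("A","C","G","T"), substr(s,400,400))[1]
  d <- pairwise_divergence(c(a = s, b = b, c = c_))
  expect_equal(sort(d$pairs$count), c(1, 2, 3))
  all_row <- d$summary[d$summary$label == "all", ]
  expect_equal(all_row$mean, 2)
  expect_equal(all_row$se, 0.5774, tolerance = 1e-3)

  ident <- pairwise_divergence(c(x = s, y = s, z = s))
  expect_equal(ident$summary$mean[ident$summary$label == "all"], 0)
  expect_equal(ident$summary$se[ident$summary$label == "all"], 0)

  expect_warning(single <- pairwise_divergence(c(only = s)), ">= 2")
  expect_equal(nrow(single$pairs), 0)
})

test_that("pairwise counts match the additive two-copy expectation", {
  # two independently mutated copies accumulate both variant sets: at rate r
  # per kb on units of L kb, a pair is expected to differ at ~2 r L sites
  L <- 4300; r <- 1.5
  ref <- with_seed(50, random_dna(L, 0.55))
  ann <- data.frame(region = "IGS", start = 1L, end = L)
  units <- with_seed(51, vapply(1:6, function(i)
    mutate_unit(ref, ann, c(IGS = r))$sequence, ""))
  names(units) <- paste0("u", 1:6)
  d <- pairwise_divergence(units)
  expected <- 2 * r * L / 1000
  got <- d$summary$mean[d$summary$label == "all"]
  expect_lt(abs(got - expected) / expected, 0.10)
})

test_that("sharing classes match the brute-force classifier", {
  groups <- c(u1 = "chr22", u2 = "chr22", u3 = "chr21", u4 = "chr21")
  sets <- list(u1 = c("k1", "k2", "k3"), u2 = c("k1", "k4"),
               u3 = c("k1", "k2"), u4 = c("k1"))
  tab <- classify_sharing(sets, groups)
  expect_equal(tab$class[tab$key == "k1"], "universal")  # all units, all groups
  expect_equal(tab$class[tab$key == "k2"], "universal")  # both groups
  expect_equal(tab$class[tab$key == "k3"], "unique")
  expect_equal(tab$class[tab$key == "k4"], "unique")
  sets$u2 <- c(sets$u2, "k3")
  tab2 <- classify_sharing(sets, groups)
  expect_equal(tab2$class[tab2$key == "k3"], "shared")  # 2 units, 1 group

  with_seed(77, {
    for (i in 1:20) {
      n_units <- sample(3:10, 1)
      units <- paste0("u", seq_len(n_units))
      gr <- setNames(sample(c("g1", "g2", "g3"), n_units, TRUE), units)
      keys <- paste0("v", 1:15)
      vs <- setNames(lapply(units, function(u)
        sample(keys, sample(0:10, 1))), units)
      got <- classify_sharing(vs, gr)
      oracle <- oracle_sharing(vs, gr)
      expect_equal(setNames(got$class, got$key), oracle[got$key])
      # classes partition the keys
      expect_equal(sort(got$key), sort(unique(unlist(vs))))
    }
  })
  expect_error(classify_sharing(list(zz = "k"), groups), "group")
})

test_that("region densities and the IGS:transcribed ratio are arithmetic", {
  ann <- data.frame(region = c("18S", "IGS"), start = c(1L, 2001L),
                    end = c(2000L, 4000L))
  v <- data.frame(pos = seq(2010, 2100, by = 10), type = "SNV", ref = "A",
                  alt = "G", region = "IGS")
  rd <- region_density(v, ann)
  expect_equal(rd$table$per_kb[rd$table$region == "IGS"], 5.0)
  expect_equal(rd$table$per_kb[rd$table$region == "18S"], 0)
  expect_equal(rd$igs_to_transcribed, Inf)

  # zero-rate region stays empty in simulation
  spec <- nor_spec(scale = 0.1, seed = 4)
  nor <- build_nor(spec)
  expect_false(any(nor$truth_variants$region == "5.8S"))

  annz <- rbind(ann, data.frame(region = "5.8S", start = 4001L, end = 4000L))
  expect_warning(region_density(v, annz), "zero-length")
})

test_that("feature mapping reports signed distances and matches brute force", {
  feats <- data.frame(name = c("CTCF", "SalT1"), start = c(100L, 300L),
                      end = c(119L, 330L))
  v <- data.frame(pos = c(110L, 70L, 340L, 500L), type = "SNV",
                  ref = "A", alt = "G", region = "IGS")
  mp <- map_to_features(v, feats, proximity = 50)
  expect_equal(mp$distance[mp$pos == 110 & mp$feature == "CTCF"], 0)
  expect_equal(mp$distance[mp$pos == 70 & mp$feature == "CTCF"], -30)
  expect_equal(mp$distance[mp$pos == 340 & mp$feature == "SalT1"], 10)
  expect_false(500 %in% mp$pos)

  bad <- data.frame(name = "x", start = 10L, end = 5L)
  expect_error(map_to_features(v, bad), "line 1")

  with_seed(90, {
    feats2 <- data.frame(name = paste0("f", 1:20),
                         start = sort(sample.int(5000, 20)))
    feats2$end <- feats2$start + sample(5:50, 20, TRUE)
    vs <- data.frame(pos = sample.int(5200, 1000, replace = TRUE),
                     type = "SNV", ref = "A", alt = "G", region = "IGS")
    got <- map_to_features(vs, feats2, proximity = 50)
    # brute-force interval scan
    exp_rows <- 0
    for (i in seq_len(nrow(vs))) for (j in seq_len(nrow(feats2))) {
      p <- vs$pos[i]
      if (p >= feats2$start[j] - 50 && p <= feats2$end[j] + 50) {
        exp_rows <- exp_rows + 1
        d <- if (p < feats2$start[j]) p - feats2$start[j]
             else if (p > feats2$end[j]) p - feats2$end[j] else 0L
        hit <- got[got$pos == p & got$feature == feats2$name[j], ]
        expect_true(all(hit$distance == d))
      }
    }
    expect_equal(nrow(got), exp_rows)
  })
})

test_that("non-homologous sequences are rejected by the band limit", {
  with_seed(3, {
    a <- random_dna(4000, 0.5)
    b <- random_dna(5000, 0.5)  # length gap alone exceeds the band limit
    expect_error(align_units(a, b, max_band = 400), "not homologous")
  })
})
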