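test_that("overlap counting uses connected components with half-open semantics", {
  expect_equal(count_overlaps(iv("c1", 0, 10), iv("c1", 5, 15)), 1)
  # one component spanning two A intervals counts once
  expect_equal(count_overlaps(iv("c1", c(0, 20), c(10, 30)), iv("c1", 5, 25)), 1)
  # half-open touching is not overlap
  expect_equal(count_overlaps(iv("c1", 0, 10), iv("c1", 10, 20)), 0)
  # symmetric by construction
  a <- iv("c1", c(0, 300), c(50, 420))
  b <- iv("c1", c(40, 310, 500), c(120, 330, 600))
  expect_equal(count_overlaps(a, b), count_overlaps(b, a))
  expect_equal(count_overlaps(a, b), 2)
  # transitive chaining collapses a run of mutual overlaps into one component
  chain_a <- iv("c1", c(0, 100), c(50, 180))
  chain_b <- iv("c1", c(40, 170), c(120, 260))
  expect_equal(count_overlaps(chain_a, chain_b), 1)
  # different chromosomes never connect
  expect_equal(count_overlaps(iv("c1", 0, 10), iv("c2", 0, 10)), 0)
  expect_error(count_overlaps(iv("c1", 10, 10), iv("c1", 0, 5)),
               "end <= start", class = "methredist_input_error")
  expect_equal(count_overlaps(iv(character(0), double(0), double(0)),
                              iv("c1", 0, 10)), 0)
})

test_that("Monte Carlo expectation matches the exhaustive placement oracle", {
  # 10 bp chromosome, A = one length-2 interval, B = [4,6): of the 9
  # placements of A, exactly 3 overlap B, so the exact expectation is 1/3
  gm <- one_chrom_genome(10)
  a <- iv("c1", 0, 2)
  b <- iv("c1", 4, 6)
  exact <- mean(vapply(0:8, function(s) {
    count_overlaps(iv("c1", s, s + 2), b)
  }, double(1)))
  expect_equal(exact, 1 / 3)
  # the enumeration oracle describes re-placements of A, so randomize A
  r <- expected_overlaps_mc(a, b, gm, n_permutations = 20000, seed = 1,
                            randomize = "a")
  se <- sqrt(exact * (1 - exact) / r$n_permutations)
  expect_lt(abs(r$expected - exact), 3 * se)
  expect_gt(r$p_value, 0)
  expect_lte(r$p_value, 1)
})

test_that("MC null handles the degenerate contracts", {
  gm <- one_chrom_genome(10)
  r_empty <- expected_overlaps_mc(iv("c1", 0, 2),
                                  iv(character(0), double(0), double(0)),
                                  gm, n_permutations = 200, seed = 1)
  expect_equal(r_empty$expected, 0)
  expect_true(is.na(r_empty$fold))
  # A covering the whole chromosome overlaps in every permutation
  r_full <- expected_overlaps_mc(iv("c1", 0, 10), iv("c1", 4, 6), gm,
                                 n_permutations = 200, seed = 1)
  expect_equal(r_full$expected, 1)
  expect_equal(r_full$p_value, 1)
  expect_error(expected_overlaps_mc(iv("c1", 0, 12), iv("c1", 4, 6), gm,
                                    n_permutations = 200),
               "longer than its chromosome", class = "methredist_input_error")
  expect_error(expected_overlaps_mc(iv("c1", 0, 2), iv("c1", 4, 6), gm,
                                    n_permutations = 50),
               class = "methredist_config_error")
})

test_that("hypergeometric overlap matches brute-force enumeration of markings", {
  # N = 10 units of 10 bp; A marks 4, B marks 5, 4 shared
  gm <- one_chrom_genome(100)
  a <- iv("c1", c(0, 10, 20, 30), c(10, 20, 30, 40))
  b <- iv("c1", c(0, 10, 20, 30, 50), c(10, 20, 30, 40, 60))
  r <- hypergeometric_overlap(a, b, gm, unit = 10)
  expect_equal(r$n_units, 10)
  expect_equal(r$n_a, 4)
  expect_equal(r$n_b, 5)
  expect_equal(r$observed, 4)
  expect_equal(r$fold, 4 / (4 * 5 / 10))  # 2.0
  expect_equal(r$p_value, 5 / 210, tolerance = 1e-12)
  # brute force: all C(10,4) A-markings against the fixed B-marking
  b_mark <- c(rep(TRUE, 5), rep(FALSE, 5))
  combos <- combn(10, 4)
  tail_p <- mean(apply(combos, 2, function(u) sum(b_mark[u])) >= 4)
  expect_equal(r$p_value, tail_p, tolerance = 1e-12)
})

test_that("hypergeometric p equals enumeration across many small universes", {
  gm <- one_chrom_genome(120)
  withr::with_seed(31, {
    for (i in 1:10) {
      ua <- sort(sample(0:11, sample(2:6, 1)))
      ub <- sort(sample(0:11, sample(2:6, 1)))
      a <- iv("c1", ua * 10, ua * 10 + 10)
      b <- iv("c1", ub * 10, ub * 10 + 10)
      r <- hypergeometric_overlap(a, b, gm, unit = 10)
      combos <- combn(12, length(ua))
      b_mark <- (0:11) %in% ub
      tail_p <- mean(apply(combos, 2, function(u) sum(b_mark[u])) >= r$observed)
      expect_equal(r$p_value, tail_p, tolerance = 1e-12)
    }
  })
  # coincident equal sets: p = 1 / C(N, n_A)
  a <- iv("c1", c(0, 20, 40), c(10, 30, 50))
  r <- hypergeometric_overlap(a, a, gm, unit = 10)
  expect_equal(r$p_value, 1 / choose(12, 3), tolerance = 1e-12)
  expect_error(hypergeometric_overlap(a, a, gm, unit = 500),
               "smallest chromosome", class = "methredist_config_error")
})

test_that("exact overlap unit: x equal to expectation gives fold 1", {
  gm <- one_chrom_genome(100)
  # N=10, n_A=5, n_B=4, x=2 = 5*4/10
  a <- iv("c1", c(0, 10, 20, 30, 40), c(10, 20, 30, 40, 50))
  b <- iv("c1", c(0, 10, 60, 70), c(10, 20, 70, 80))
  r <- hypergeometric_overlap(a, b, gm, unit = 10)
  expect_equal(r$fold, 1.0)
})

test_that("co-occurrence folds are symmetric and cluster perturbed copies", {
  gm <- genome_model(tibble::tibble(chrom = c("c1", "c2"),
                                    length = c(20000, 20000)))
  withr::with_seed(9, {
    s1 <- iv("c1", seq(0, 19000, by = 1000) + sample(0:200, 20, replace = TRUE), 0)
    s1$end <- s1$start + 300
    s2 <- s1
    s2$start <- s2$start + sample(-50:50, 20, replace = TRUE)
    s2$end <- s2$start + 300
    s3 <- iv("c2", seq(0, 19000, by = 2000) + sample(0:500, 10, replace = TRUE), 0)
    s3$end <- s3$start + 300
    cm <- cooccurrence_matrix(list(copy1 = s1, copy2 = s2, other = s3), gm,
                              n_permutations = 200, seed = 4)
    expect_equal(cm$fold, t(cm$fold))
    # identical-set fold: two copies overlap each other about as strongly as
    # themselves
    expect_gt(cm$fold["copy1", "copy2"], 2)
    # disjoint chromosomes: no overlap possible, fold 0
    expect_equal(cm$fold["copy1", "other"], 0)
    # clustering puts the perturbed copies adjacent
    o <- match(c("copy1", "copy2"), cm$leaf_order)
    expect_equal(abs(diff(o)), 1)
  })
})

test_that("two identical sets have mutual fold equal to self fold", {
  gm <- one_chrom_genome(5000)
  s <- iv("c1", c(100, 900, 2000), c(300, 1200, 2500))
  r_self <- expected_overlaps_mc(s, s, gm, n_permutations = 500, seed = 2)
  expect_equal(r_self$observed, 3)
  cm <- suppressWarnings(
    cooccurrence_matrix(list(a = s, b = s), gm, n_permutations = 300, seed = 2)
  )
  expect_equal(cm$observed["a", "b"], cm$observed["a", "a"])
  expect_equal(cm$fold["a", "b"], cm$fold["b", "a"])
})

test_that("empty sets are flagged missing in the matrix", {
  gm <- one_chrom_genome(5000)
  s <- iv("c1", c(100, 900), c(300, 1200))
  expect_warning(
    cm <- cooccurrence_matrix(list(a = s, b = s,
                                   none = iv(character(0), double(0), double(0))),
                              gm, n_permutations = 150, seed = 1),
    "empty"
  )
  expect_true(all(is.na(cm$fold["none", ])))
  expect_false("none" %in% cm$leaf_order)
})

test_that("MC overlap p-values are calibrated under the null", {
  # independent random placements of both sets: empirical type-I error at
  # alpha = 0.05 stays at or below ~nominal over 500 replicates
  gm <- genome_model(tibble::tibble(chrom = c("c1", "c2"),
                                    length = c(50000, 50000)))
  reject <- withr::with_seed(123, {
    vapply(1:500, function(i) {
      na <- 8; nb <- 8
      ca <- sample(c("c1", "c2"), na, replace = TRUE)
      cb <- sample(c("c1", "c2"), nb, replace = TRUE)
      a <- iv(ca, floor(runif(na, 0, 49800)), 0); a$end <- a$start + 200
      b <- iv(cb, floor(runif(nb, 0, 49800)), 0); b$end <- b$start + 200
      r <- expected_overlaps_mc(a, b, gm, n_permutations = 100, seed = i,
                                randomize = "a")
      r$p_value <= 0.05
    }, logical(1))
  })
  expect_lte(mean(reject), 0.07)
})
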