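test_that("context assignment follows the three-context rule on both strands", {
  expect_equal(assign_context("ACGT", 1), "CG")
  expect_equal(assign_context("ACAGT", 1), "CHG")
  expect_equal(assign_context("ACATT", 1), "CHH")
  expect_equal(assign_context("ACGT", 2, "-"), "CG")
  expect_equal(assign_context("CTGA", 2, "-"), "CHG")  # minus read: C,A,G
  expect_true(is.na(assign_context("ACGT", 0)))        # A is not a cytosine
  expect_true(is.na(assign_context("ACGT", 1, "-")))   # C is not a minus-strand cytosine
  # within 2 bp of the readable 3' end: undetermined, never guessed
  expect_equal(assign_context("AC", 1), "undetermined")
  expect_equal(assign_context("ACA", 1), "undetermined")
  expect_equal(assign_context("GA", 0, "-"), "undetermined")
  expect_error(assign_context("ACGT", 4), "out of bounds",
               class = "methredist_input_error")
})

test_that("CG sites are strand-symmetric in random sequence", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
      plus_cg <- which(assign_context(s, 0:498, "+") == "CG") - 1
      for (p in plus_cg) {
        expect_equal(assign_context(s, p + 1, "-"), "CG")
      }
    }
  })
})

test_that("unconverted-read filter removes >= 3 consecutive methylated CHH calls", {
  # consecutive means adjacent CHH calls in read order, other contexts ignored
  expect_true(is_unconverted("HHH"))
  expect_false(is_unconverted("HHhH"))      # max run 2
  expect_false(is_unconverted("ZZZZZ"))     # CG-only methylation is not failure
  expect_true(is_unconverted("HZxHzH"))     # interleaved CG/CHG do not break the run
  expect_false(is_unconverted("HHxZh"))
  expect_false(is_unconverted(""))
  f <- filter_unconverted_reads(c("HHH", "HHhH", "ZZZZZ", "HZHZH"))
  expect_equal(f$kept, c("HHhH", "ZZZZZ"))
  expect_equal(f$removed, c("HHH", "HZHZH"))
  # data-frame input keeps all columns and the original order
  reads <- simulate_reads_with_conversion_failure(200, 6, 0.3, seed = 2)
  f2 <- filter_unconverted_reads(reads)
  expect_setequal(c(f2$kept$read_id, f2$removed$read_id), reads$read_id)
  expect_true(all(is_unconverted(f2$removed$calls)))
  expect_true(all(!f2$kept$failed))  # at 6 sites every true failure is caught
})

test_that("filter is monotone: adding methylated CHH calls never rescues a read", {
  withr::with_seed(7, {
    pool <- c("H", "h", "Z", "z", "X", "x")
    for (i in 1:50) {
      r <- paste(sample(pool, 8, replace = TRUE), collapse = "")
      if (is_unconverted(r)) {
        expect_true(is_unconverted(paste0(r, "H")))
        expect_true(is_unconverted(paste0("H", r)))
      }
    }
  })
})

test_that("methylation level arithmetic matches its definition", {
  expect_equal(methylation_level(3, 1), 0.75)
  expect_equal(methylation_level(0, 7), 0)
  expect_true(is.na(methylation_level(0, 0)))
  expect_equal(methylation_level(c(3, 0, 0), c(1, 7, 0)), c(0.75, 0, NA))
  expect_error(methylation_level(-1, 2), "non-negative",
               class = "methredist_input_error")
})

test_that("window pooling is depth-weighted and flags empty windows", {
  gm <- one_chrom_genome(25000, "chr1")
  report <- tibble::tibble(
    chrom = "chr1", pos = c(100, 200, 12000), strand = "+",
    context = "CG", n_meth = c(3, 1, 10), n_unmeth = c(1, 3, 0)
  )
  w <- window_methylation(report, gm, window = 10000, context = "CG")
  expect_equal(nrow(w), 3)
  expect_equal(w$level[1], 0.5)   # (3+1)/(4+4)
  expect_equal(w$level[2], 1.0)   # fully methylated
  expect_true(is.na(w$level[3]))  # no cytosines: missing, not 0
  expect_equal(w$n_cytosines, c(2L, 1L, 0L))
  # final partial window keeps its true span
  expect_equal(w$end[3], 25000)
  # pooling consistency: window level == methylation_level of summed counts
  expect_equal(w$level[1], methylation_level(3 + 1, 1 + 3))
  expect_error(window_methylation(report, gm, context = "CCC"),
               "unknown context", class = "methredist_input_error")
  expect_error(window_methylation(report, gm, window = 0),
               class = "methredist_input_error")
})

test_that("per-site pooling option averages unweighted levels", {
  gm <- one_chrom_genome(1000, "chr1")
  report <- tibble::tibble(
    chrom = "chr1", pos = c(1, 2), strand = "+", context = "CG",
    n_meth = c(9, 0), n_unmeth = c(1, 10)
  )
  w_depth <- window_methylation(report, gm, window = 1000, context = "CG")
  w_site <- window_methylation(report, gm, window = 1000, context = "CG",
                               pool = "site")
  expect_equal(w_depth$level, 9 / 20)
  expect_equal(w_site$level, (0.9 + 0) / 2)
})

test_that("conversion rate comes from the control contig", {
  report <- tibble::tibble(
    chrom = c("ctrl", "ctrl", "chr1"), pos = c(0, 5, 0), strand = "+",
    context = "CHH", n_meth = c(5, 0, 50), n_unmeth = c(495, 500, 0)
  )
  expect_equal(conversion_rate(report, "ctrl"), 0.995)
  full <- tibble::tibble(chrom = "ctrl", pos = 0:9, strand = "+",
                         context = "CG", n_meth = 0, n_unmeth = 10)
  expect_equal(conversion_rate(full, "ctrl"), 1.0)
  expect_error(conversion_rate(report, "chloro"), "absent",
               class = "methredist_input_error")
})

test_that("simulated conversion failures are recovered within binomial error", {
  # failure 0.02 at depth 30 over ~6k control cytosines: SE well under 0.005
  cfg <- tiny_config(conversion_failure_rate = 0.02)
  g <- make_genome(cfg)
  tes <- place_tes(g, cfg)
  r <- simulate_methylome(g, tes, "WT", cfg)
  est <- conversion_rate(r, "ctrl")
  expect_lt(abs(est - 0.98), 0.005)
})
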