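flat_track <- function(value, len = 1000, chrom = "c1") {
  tibble::tibble(chrom = chrom, start = 0, end = len, value = value)
}

test_that("normalization against self or a scaled copy is identically zero", {
  withr::with_seed(8, {
    x <- rle_track <- tibble::tibble(
      chrom = "c1", start = seq(0, 900, by = 100), end = seq(100, 1000, by = 100),
      value = rpois(10, 5) + 1
    )
    z <- normalize_track(x, x, "log2_ratio")
    expect_true(all(z$value == 0))
    # uniform 2x chip collapses to zero after read-count scaling + subtract
    x2 <- x; x2$value <- x2$value * 2
    z2 <- normalize_track(x2, x, "subtract")
    expect_true(all(abs(z2$value) < 1e-12))
  })
})

test_that("log2 ratio arithmetic and error contracts hold", {
  chip <- flat_track(4)
  ref <- flat_track(4)  # equal masses, so no rescaling
  chip$value <- 4; ref$value <- 1
  # force equal masses by construction: use a two-run design summing equal
  chip <- tibble::tibble(chrom = "c1", start = c(0, 500), end = c(500, 1000),
                         value = c(4, 1))
  ref <- tibble::tibble(chrom = "c1", start = c(0, 500), end = c(500, 1000),
                        value = c(1, 4))
  z <- normalize_track(chip, ref, "log2_ratio", pseudocount = 1)
  expect_equal(z$value[z$start == 0], log2(5 / 2), tolerance = 1e-12)
  expect_error(normalize_track(chip, flat_track(0)), "zero",
               class = "methredist_input_error")
  bad <- tibble::tibble(chrom = "c1", start = c(0, 50), end = c(100, 150),
                        value = 1)
  expect_error(normalize_track(bad, ref), "overlapping",
               class = "methredist_input_error")
})

test_that("peak calling thresholds, widths and merging behave as specified", {
  base <- tibble::tibble(chrom = "c1",
                         start = c(0, 100, 160, 200, 260, 900),
                         end = c(100, 160, 200, 260, 900, 1000),
                         value = c(0.1, 3, 0.2, 3, 0.1, 0.2))
  expect_equal(nrow(call_enriched_peaks(flat_track(0.5), threshold = 1)), 0)
  # one rectangular bump keeps its exact coordinates
  p1 <- call_enriched_peaks(base, threshold = 1, min_width = 10, merge_gap = 0)
  expect_equal(p1$start, c(100, 200))
  expect_equal(p1$end, c(160, 260))
  # two bumps closer than merge_gap fuse
  p2 <- call_enriched_peaks(base, threshold = 1, min_width = 10, merge_gap = 50)
  expect_equal(nrow(p2), 1)
  expect_equal(c(p2$start, p2$end), c(100, 260))
  # short runs are dropped
  p3 <- call_enriched_peaks(base, threshold = 1, min_width = 100)
  expect_equal(nrow(p3), 0)
})

test_that("differential regions are empty under the null and antisymmetric", {
  gm <- one_chrom_genome(10000)
  withr::with_seed(3, {
    v <- rpois(100, 4)
    a <- tibble::tibble(chrom = "c1", start = seq(0, 9900, by = 100),
                        end = seq(100, 10000, by = 100), value = v)
    expect_s3_class(dr0 <- differential_regions(a, a, gm), "diff_regions")
    expect_equal(nrow(dr0$gain), 0)
    expect_equal(nrow(dr0$loss), 0)
    b <- a; b$value <- rev(v)
    d_ab <- differential_regions(a, b, gm)
    d_ba <- differential_regions(b, a, gm)
    expect_identical(d_ab$gain, d_ba$loss)
    expect_identical(d_ab$loss, d_ba$gain)
  })
})

test_that("programmed heterochromatic body gain is recovered as gain regions", {
  cfg <- tiny_config()
  g <- make_genome(cfg)
  tes <- place_tes(g, cfg)
  tr_wt <- simulate_chip_track(g, tes, "WT", cfg)
  tr_h1 <- simulate_chip_track(g, tes, "h1", cfg)
  dr <- differential_regions(tr_h1, tr_wt, g)
  cov_frac <- function(set) {
    vapply(seq_len(nrow(set)), function(i) {
      seg <- dr$gain[dr$gain$chrom == set$chrom[i] &
                       dr$gain$end > set$start[i] &
                       dr$gain$start < set$end[i], , drop = FALSE]
      if (nrow(seg) == 0) return(0)
      sum(pmin(seg$end, set$end[i]) - pmax(seg$start, set$start[i])) /
        (set$end[i] - set$start[i])
    }, double(1))
  }
  het <- cov_frac(tes[tes$class == "heterochromatic", ])
  eu <- cov_frac(tes[tes$class == "euchromatic", ])
  expect_gte(mean(het >= 0.5), 0.9)
  expect_lte(mean(eu >= 0.5), 0.05)
})

test_that("bedGraph round-trips run-length tracks losslessly", {
  cfg <- tiny_config()
  g <- make_genome(cfg)
  tes <- place_tes(g, cfg)
  tr <- simulate_chip_track(g, tes, "WT", cfg)
  f <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f)
  expect_equal(as.data.frame(back), as.data.frame(tr))
})
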