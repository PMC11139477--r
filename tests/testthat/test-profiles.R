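test_that("metaprofile of a constant track is constant", {
  track <- tibble::tibble(chrom = "c1", start = 0, end = 10000, value = 2)
  feats <- iv("c1", c(2000, 6000), c(3000, 7500))
  mp <- metaprofile(track, feats, flank = 500, n_body_bins = 10, n_flank_bins = 5)
  expect_true(all(abs(mp$mean_signal - 2) < 1e-12))
  expect_equal(nrow(mp), 20)
  expect_equal(unique(mp$n_features), 2L)
})

test_that("features shorter than the bin count contribute via interpolation", {
  track <- tibble::tibble(chrom = "c1", start = c(0, 100), end = c(100, 200),
                          value = c(1, 3))
  feats <- iv("c1", 95, 105)  # 10 bp body, 20 body bins
  mp <- metaprofile(track, feats, flank = 0, n_body_bins = 20)
  expect_equal(nrow(mp), 20)
  expect_false(any(is.na(mp$mean_signal)))
  expect_equal(mp$mean_signal[1], 1)
  expect_equal(mp$mean_signal[20], 3)
  expect_true(all(diff(mp$mean_signal) >= 0))
})

test_that("strand awareness reverses a single feature's bin order", {
  withr::with_seed(2, {
    track <- tibble::tibble(chrom = "c1", start = seq(0, 1900, by = 100),
                            end = seq(100, 2000, by = 100),
                            value = runif(20))
    plus <- tibble::tibble(chrom = "c1", start = 500, end = 1500, strand = "+")
    minus <- dplyr::mutate(plus, strand = "-")
    mp_plus <- metaprofile(track, plus, flank = 200, n_body_bins = 10,
                           n_flank_bins = 2, strand_aware = TRUE)
    mp_minus <- metaprofile(track, minus, flank = 200, n_body_bins = 10,
                            n_flank_bins = 2, strand_aware = TRUE)
    expect_equal(mp_plus$mean_signal, rev(mp_minus$mean_signal))
    # unstranded default ignores strand entirely
    mp_un <- metaprofile(track, minus, flank = 200, n_body_bins = 10,
                         n_flank_bins = 2)
    expect_equal(mp_un$mean_signal, mp_plus$mean_signal)
  })
})

test_that("occupancy metaprofiles show the programmed edge and body patterns", {
  cfg <- tiny_config()
  g <- make_genome(cfg)
  tes <- place_tes(g, cfg)
  long <- tes[tes$lenclass == "long", ]
  wt <- simulate_chip_track(g, tes, "WT", cfg)
  h1 <- simulate_chip_track(g, tes, "h1", cfg)
  mp_wt <- metaprofile(wt, long, flank = 1000, n_body_bins = 20)
  mp_h1 <- metaprofile(h1, long, flank = 1000, n_body_bins = 20)
  body_idx <- which(mp_wt$segment == "body")
  edge_bins <- body_idx[c(1, 20)]
  central_bins <- body_idx[8:13]
  # WT: edges above body centre
  expect_gt(mean(mp_wt$mean_signal[edge_bins]),
            mean(mp_wt$mean_signal[central_bins]))
  # h1: body centre above the WT body centre
  expect_gt(mean(mp_h1$mean_signal[central_bins]),
            mean(mp_wt$mean_signal[central_bins]))
})

test_that("per-feature enrichment is a width-weighted mean with missing contract", {
  track <- tibble::tibble(chrom = "c1", start = c(0, 50), end = c(50, 100),
                          value = c(0, 4))
  feats <- iv("c1", c(0, 0, 200), c(100, 50, 300))
  s <- per_feature_enrichment(track, feats)
  expect_equal(s$mean_signal, c(2, 0, NA_real_))
  # constant track over feature
  s2 <- per_feature_enrichment(tibble::tibble(chrom = "c1", start = 0,
                                              end = 300, value = 3),
                               iv("c1", 10, 200))
  expect_equal(s2$mean_signal, 3)
})

test_that("enrichment is invariant to splitting runs (mean associativity)", {
  withr::with_seed(6, {
    v <- runif(10)
    whole <- tibble::tibble(chrom = "c1", start = seq(0, 90, 10),
                            end = seq(10, 100, 10), value = v)
    split2 <- tibble::tibble(chrom = "c1", start = seq(0, 95, 5),
                             end = seq(5, 100, 5), value = rep(v, each = 2))
    f <- iv("c1", 0, 100)
    expect_equal(per_feature_enrichment(whole, f)$mean_signal,
                 per_feature_enrichment(split2, f)$mean_signal)
  })
})

test_that("class comparison reports exact symmetric cases and programmed shifts", {
  s <- tibble::tibble(cls = rep(c("x", "y"), each = 3),
                      mean_signal = c(1, 2, 3, 1, 2, 3))
  cc <- class_comparison(s, "cls")
  expect_equal(cc$p_value, 1)
  expect_equal(cc$direction, 0)
  # two singleton classes: enumeration gives p = 1
  s2 <- tibble::tibble(cls = c("x", "y"), mean_signal = c(1, 2))
  expect_equal(class_comparison(s2, "cls")$p_value, 1)
  # an all-missing class is excluded with a warning; comparison proceeds
  s3 <- tibble::tibble(cls = c("x", "x", "y", "y", "z"),
                       mean_signal = c(1, 2, 3, 4, NA))
  expect_warning(cc3 <- class_comparison(s3, "cls"), "no members")
  expect_equal(nrow(cc3), 1)
  expect_error(
    suppressWarnings(class_comparison(
      tibble::tibble(cls = c("x", "x", "y"), mean_signal = c(1, 2, NA)), "cls"
    )),
    class = "methredist_input_error"
  )
})

test_that("h1 occupancy separates chromatin classes with programmed direction", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 80000,
                    n_short_te = 30, n_long_te = 30,
                    long_te_length = c(700, 1200),
                    short_te_length = c(200, 600), seed = 19)
  g <- make_genome(cfg)
  tes <- place_tes(g, cfg)
  h1 <- simulate_chip_track(g, tes, "h1", cfg)
  enr <- per_feature_enrichment(h1, tes)
  cc <- class_comparison(enr, "class")
  expect_gte(min(cc$n_a, cc$n_b), 30)
  expect_lt(cc$p_value, 0.01)
  med_het <- with(cc, ifelse(class_a == "heterochromatic", median_a, median_b))
  med_eu <- with(cc, ifelse(class_a == "heterochromatic", median_b, median_a))
  expect_gt(med_het, med_eu)
})

test_that("per-TE methylation differences recover programmed shifts", {
  cfg <- tiny_config()
  g <- make_genome(cfg)
  tes <- place_tes(g, cfg)
  wt <- simulate_methylome(g, tes, "WT", cfg)
  # A = B gives all-zero differences
  d0 <- methylation_difference_density(wt, wt, tes, "CHG")
  expect_true(all(d0$diff == 0, na.rm = TRUE))
  h1 <- simulate_methylome(g, tes, "h1", cfg)
  d <- methylation_difference_density(h1, wt, tes, "CHG")
  het_diff <- d$diff[d$class == "heterochromatic"]
  # programmed +0.20 CHG gain in heterochromatin (0.85 vs 0.65)
  expect_lt(abs(mean(het_diff, na.rm = TRUE) - 0.20), 0.05)
  # a feature with no covered cytosines is missing
  far <- iv("chr1", 0, 5)
  wt_chg <- wt[wt$context == "CHG" & (wt$pos >= 5 | wt$chrom != "chr1"), ]
  dmiss <- methylation_difference_density(wt_chg, wt_chg, far, "CHG")
  expect_true(is.na(dmiss$diff))
})

test_that("chromosomal profiles annotate compartments by window midpoint", {
  gm <- genome_model(tibble::tibble(chrom = "c1", length = 100000),
                     tibble::tibble(chrom = "c1", start = 35000, end = 65000))
  flat <- tibble::tibble(chrom = "c1", start = 0, end = 100000, value = 1)
  cp <- chromosomal_profile(flat, gm, window = 10000)
  expect_true(all(cp$value == 1))
  expect_equal(cp$compartment,
               c("arm", "arm", "arm", "pericentromere", "pericentromere",
                 "pericentromere", "arm", "arm", "arm", "arm"))
  # midpoint exactly at the pericentromere start is pericentromeric
  gm2 <- genome_model(tibble::tibble(chrom = "c1", length = 40000),
                      tibble::tibble(chrom = "c1", start = 15000, end = 30000))
  cp2 <- chromosomal_profile(flat[, ], gm2, window = 10000)
  expect_equal(cp2$compartment[2], "pericentromere")  # midpoint 15000
})

test_that("h1 - WT difference is concentrated in pericentromeres", {
  cfg <- tiny_config()
  g <- make_genome(cfg)
  tes <- place_tes(g, cfg)
  diff_track <- normalize_track(simulate_chip_track(g, tes, "h1", cfg),
                                simulate_chip_track(g, tes, "WT", cfg),
                                "subtract")
  cp <- chromosomal_profile(diff_track, g, window = 10000)
  expect_gt(mean(cp$value[cp$compartment == "pericentromere"]),
            mean(cp$value[cp$compartment == "arm"]))
})
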