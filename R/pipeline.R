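#' Run the full synthetic redistribution pipeline
#'
#' Chains every stage of the package on one simulated dataset: genome and TE
#' simulation, occupancy tracks (WT, h1, input) and methylomes (WT, h1,
#' nrpe1, h1_nrpe1), ChIP-vs-input normalization, differential occupancy
#' regions (h1 vs WT), DMR calling per context for each mutant against WT,
#' DMR co-occurrence statistics, hypergeometric overlap of occupancy-gain
#' regions with heterochromatic TEs, metaprofiles, class comparisons,
#' per-TE methylation differences, chromosomal profiles, and conversion-rate
#' estimates. All stage outputs are written as plain-text BED / bedGraph /
#' FASTA / TSV under `out_dir`, together with a log echoing the seed and
#' parameters; rerunning with the same configuration reproduces the outputs
#' byte-identically. On failure, partial outputs are removed.
#'
#' @param config A [sim_config()]; its seed drives every stage.
#' @param out_dir Output directory (created if needed).
#' @param dmr_comparisons Genotypes to call DMRs for against WT.
#' @param n_permutations Monte Carlo permutations per direction for the
#'   co-occurrence statistics.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the main result objects: `genome`, `tes`,
#'   `tracks`, `normalized`, `diff_regions`, `dmrs` (list by
#'   comparison/context), `dmr_sets`, `cooccurrence`, `hyperg_gain_het`,
#'   `profiles`, `class_cmp`, `chrom_profile`, `meth_diff`,
#'   `conversion_rates`, and a one-row `summary` tibble of headline numbers.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("methredist_"),
                         dmr_comparisons = c("h1", "nrpe1", "h1_nrpe1"),
                         n_permutations = 200, quiet = FALSE) {
  validate_sim_config(config)
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  written <- character(0)
  on.exit({
    if (!ok) {
      unlink(written)
      if (created) unlink(out_dir, recursive = TRUE)
    }
  }, add = TRUE)
  emit <- function(...) if (!quiet) message(sprintf(...))
  save_file <- function(writer, obj, name) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    written <<- c(written, p)
    p
  }

  emit("simulate: genome (%d x %d bp) + TEs", config$n_chromosomes, config$chrom_length)
  genome <- make_genome(config)
  tes <- place_tes(genome, config)
  save_file(write_genome_fasta, genome, "genome.fa")
  save_file(write_bed, tes, "tes.bed")

  emit("simulate: occupancy tracks and methylomes")
  tracks <- list(
    WT = simulate_chip_track(genome, tes, "WT", config),
    h1 = simulate_chip_track(genome, tes, "h1", config),
    input = simulate_chip_track(genome, tes, "input", config)
  )
  for (g in names(tracks)) {
    save_file(write_bedgraph, tracks[[g]], sprintf("chip_%s.bedgraph", g))
  }
  genotypes <- unique(config$meth_params$genotype)
  reports <- lapply(setNames(genotypes, genotypes), function(g) {
    simulate_methylome(genome, tes, g, config)
  })
  for (g in genotypes) {
    save_file(write_cytosine_report, reports[[g]], sprintf("meth_%s.tsv", g))
  }
  conversion_rates <- vapply(reports, conversion_rate,
                             control_contig = genome$model$control_contig, double(1))

  emit("extract: normalization + differential occupancy")
  normalized <- list(
    WT = normalize_track(tracks$WT, tracks$input, "log2_ratio"),
    h1 = normalize_track(tracks$h1, tracks$input, "log2_ratio")
  )
  for (g in names(normalized)) {
    save_file(write_bedgraph, normalized[[g]], sprintf("norm_%s.bedgraph", g))
  }
  dr <- differential_regions(tracks$h1, tracks$WT, genome)
  save_file(write_bed, dr$gain, "nrpe1_gain_regions.bed")
  save_file(write_bed, dr$loss, "nrpe1_loss_regions.bed")

  emit("dmr: windowed exact-test calling vs WT")
  dmrs <- list()
  for (g in intersect(dmr_comparisons, setdiff(genotypes, "WT"))) {
    for (ctx in c("CG", "CHG", "CHH")) {
      dmrs[[paste(g, ctx, sep = "_")]] <-
        call_dmrs(reports[[g]], reports$WT, ctx, genome)
    }
  }
  dmr_stats <- purrr::imap_dfr(dmrs, ~ mutate(glance(.x), comparison = .y))
  save_file(function(o, p) readr::write_tsv(o, p), dmr_stats, "dmr_counts.tsv")
  for (nm in names(dmrs)) {
    d <- dmrs[[nm]]
    if (nrow(d) == 0) next
    bed <- d |>
      mutate(name = paste0(.data$context, ":", .data$direction),
             score = round(-log10(pmax(.data$p_adj, 1e-300)), 2), strand = ".") |>
      select("chrom", "start", "end", "name", "score", "strand")
    save_file(write_bed, bed, sprintf("dmr_%s_vs_WT.bed", nm))
    save_file(function(o, p) readr::write_tsv(o, p), as_tibble(d),
              sprintf("dmr_%s_vs_WT.tsv", nm))
  }

  emit("overlap: co-occurrence + hypergeometric enrichment")
  dmr_sets <- list()
  for (nm in names(dmrs)) {
    d <- dmrs[[nm]]
    for (dir in c("hyper", "hypo")) {
      s <- as_tibble(d[d$direction == dir, c("chrom", "start", "end")])
      if (nrow(s) > 0) dmr_sets[[paste(nm, dir, sep = "_")]] <- s
    }
  }
  te_sets <- list(
    het_te = tes[tes$class == "heterochromatic", c("chrom", "start", "end")],
    eu_te = tes[tes$class == "euchromatic", c("chrom", "start", "end")]
  )
  cooc <- NULL
  if (length(dmr_sets) >= 2) {
    cooc <- cooccurrence_matrix(c(dmr_sets, te_sets), genome,
                                n_permutations = n_permutations,
                                seed = substream_seed(config$seed, "cooccurrence"))
    save_file(function(o, p) readr::write_tsv(o, p), tidy(cooc), "cooccurrence.tsv")
    save_file(function(o, p) readr::write_lines(o, p), cooc$leaf_order,
              "cooccurrence_leaf_order.txt")
  }
  hyperg <- hypergeometric_overlap(dr$gain, te_sets$het_te, genome, unit = 1000)
  hyperg_loss <- hypergeometric_overlap(dr$loss, te_sets$eu_te, genome, unit = 1000)
  save_file(function(o, p) readr::write_tsv(o, p),
            bind_rows(mutate(tidy(hyperg), comparison = "gain_vs_het_te"),
                      mutate(tidy(hyperg_loss), comparison = "loss_vs_eu_te")),
            "hypergeometric_overlaps.tsv")

  emit("profile: metaprofiles, class comparisons, chromosomal views")
  long_tes <- tes[tes$lenclass == "long", , drop = FALSE]
  profiles <- list(
    WT_long_te = metaprofile(normalized$WT, long_tes),
    h1_long_te = metaprofile(normalized$h1, long_tes)
  )
  prof_tbl <- purrr::imap_dfr(profiles, ~ mutate(as_tibble(.x), track = .y))
  save_file(function(o, p) readr::write_tsv(o, p), prof_tbl, "metaprofiles.tsv")
  enr <- per_feature_enrichment(normalized$h1, tes)
  class_cmp <- class_comparison(enr, "class")
  save_file(function(o, p) readr::write_tsv(o, p), class_cmp, "class_comparison.tsv")
  diff_track <- normalize_track(tracks$h1, tracks$WT, "subtract")
  chrom_profile <- chromosomal_profile(diff_track, genome)
  save_file(function(o, p) readr::write_tsv(o, p), chrom_profile,
            "chromosomal_profile_h1_minus_WT.tsv")
  meth_diff <- methylation_difference_density(reports$h1, reports$WT, tes, "CHG")
  save_file(function(o, p) readr::write_tsv(o, p), meth_diff,
            "te_methylation_difference_h1_vs_WT_CHG.tsv")

  # headline numbers
  body_covered <- function(set, regions) {
    if (nrow(set) == 0) return(NA_real_)
    vapply(seq_len(nrow(set)), function(i) {
      seg <- regions[regions$chrom == set$chrom[i] &
                       regions$end > set$start[i] &
                       regions$start < set$end[i], , drop = FALSE]
      if (nrow(seg) == 0) return(0)
      sum(pmin(seg$end, set$end[i]) - pmax(seg$start, set$start[i])) /
        (set$end[i] - set$start[i])
    }, double(1))
  }
  het_cov <- body_covered(tes[tes$class == "heterochromatic", ], dr$gain)
  eu_cov <- body_covered(tes[tes$class == "euchromatic", ], dr$gain)
  pc_mean <- mean(chrom_profile$value[chrom_profile$compartment == "pericentromere"],
                  na.rm = TRUE)
  arm_mean <- mean(chrom_profile$value[chrom_profile$compartment == "arm"],
                   na.rm = TRUE)
  summary <- tibble(
    n_gain_regions = nrow(dr$gain),
    n_loss_regions = nrow(dr$loss),
    frac_het_te_recovered = mean(het_cov >= 0.5),
    frac_eu_te_called_gain = mean(eu_cov >= 0.5),
    n_h1_hyper_chg_dmrs = sum(dmrs[["h1_CHG"]]$direction == "hyper"),
    n_nrpe1_hypo_chh_dmrs = sum(dmrs[["nrpe1_CHH"]]$direction == "hypo"),
    gain_vs_het_te_fold = hyperg$fold,
    gain_vs_het_te_log10p = log10(pmax(hyperg$p_value, 1e-300)),
    class_cmp_p = class_cmp$p_value[1],
    pericen_minus_arm_diff = pc_mean - arm_mean,
    conversion_rate_wt = unname(conversion_rates["WT"])
  )
  save_file(function(o, p) readr::write_tsv(o, p), summary, "summary.tsv")

  log_lines <- c(
    sprintf("methredist %s", as.character(utils::packageVersion("methredist"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("date %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed %d", config$seed),
    "config:",
    utils::capture.output(utils::str(config[setdiff(names(config),
                                                    c("meth_params", "chip_params"))])),
    "meth_params:",
    readr::format_tsv(config$meth_params),
    "chip_params:",
    readr::format_tsv(config$chip_params)
  )
  readr::write_lines(log_lines, file.path(out_dir, "pipeline_log.txt"))
  written <- c(written, file.path(out_dir, "pipeline_log.txt"))

  ok <- TRUE
  emit("report: done, outputs in %s", out_dir)
  invisible(list(
    genome = genome, tes = tes, tracks = tracks, normalized = normalized,
    diff_regions = dr, dmrs = dmrs, dmr_sets = dmr_sets, cooccurrence = cooc,
    hyperg_gain_het = hyperg, hyperg_loss_eu = hyperg_loss,
    profiles = profiles, class_cmp = class_cmp, chrom_profile = chrom_profile,
    meth_diff = meth_diff, conversion_rates = conversion_rates,
    summary = summary, out_dir = out_dir
  ))
}
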