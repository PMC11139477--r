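# Compartment of each position: heterochromatic / euchromatic TE body, or
# background. `pos` 0-based within one chromosome.
compartment_of <- function(pos, tes) {
  out <- rep("background", length(pos))
  for (i in seq_len(nrow(tes))) {
    inside <- pos >= tes$start[i] & pos < tes$end[i]
    out[inside] <- tes$class[i]
  }
  out
}

# Beta-binomial draw with mean m and overdispersion rho (rho -> 0 degenerates
# to the binomial). Parameterization: p ~ Beta(a, b) with a + b = (1 - rho)/rho.
rbetabinom <- function(n, size, m, rho) {
  p <- numeric(n)
  plain <- rho == 0 | m == 0 | m == 1
  if (any(plain)) p[plain] <- m[plain]
  if (any(!plain)) {
    s <- (1 - rho[!plain]) / rho[!plain]
    p[!plain] <- rbeta(sum(!plain), m[!plain] * s, (1 - m[!plain]) * s)
  }
  rbinom(n, size, p)
}

#' Simulate a genotype's methylome as a cytosine report
#'
#' Scans the simulated genome for cytosines on both strands, assigns each its
#' sequence context and chromatin compartment (heterochromatic TE body,
#' euchromatic TE body, or background), and draws methylated counts from a
#' beta-binomial with the configured mean, overdispersion and depth for the
#' genotype x context x compartment combination. The unmethylated control
#' contig is simulated at the conversion-failure rate only, so that
#' [conversion_rate()] can be exercised. Deterministic under the
#' configuration seed with one substream per genotype; methylated plus
#' unmethylated counts always equal the configured depth.
#'
#' @param genome A `sim_genome` (sequences are required).
#' @param features TE feature tibble from [place_tes()].
#' @param genotype A genotype present in `config$meth_params` (defaults:
#'   `WT`, `h1`, `nrpe1`, `h1_nrpe1`).
#' @param config The [sim_config()].
#' @return A cytosine report tibble: `chrom`, `pos` (0-based), `strand`,
#'   `context`, `n_meth`, `n_unmeth`.
#' @export
simulate_methylome <- function(genome, features, genotype, config) {
  validate_sim_config(config)
  if (!inherits(genome, "sim_genome")) {
    stop_input("`genome` must be a sim_genome (sequences are needed)")
  }
  gm <- genome$model
  mp <- config$meth_params[config$meth_params$genotype == genotype, , drop = FALSE]
  if (nrow(mp) == 0) {
    stop_config("no meth_params entries for genotype '%s' (available: %s)",
                genotype, paste(unique(config$meth_params$genotype), collapse = ", "))
  }
  need <- tidyr::crossing(context = c("CG", "CHG", "CHH"),
                          compartment = c("heterochromatic", "euchromatic", "background"))
  missing <- dplyr::anti_join(need, mp, by = c("context", "compartment"))
  if (nrow(missing) > 0) {
    stop_config("meth_params for genotype '%s' is missing %s",
                genotype,
                paste(missing$context, missing$compartment, sep = "/", collapse = ", "))
  }
  ctrl <- gm$control_contig
  withr::with_seed(substream_seed(config$seed, paste0("meth_", genotype)), {
    purrr::map_dfr(gm$chromosomes$chrom, function(ch) {
      cyt <- contexts_for_seq(genome$seq[[ch]])
      if (nrow(cyt) == 0) return(tibble())
      if (!is.na(ctrl) && ch == ctrl) {
        depth <- as.integer(round(mean(mp$depth)))
        n_meth <- rbinom(nrow(cyt), depth, config$conversion_failure_rate)
        return(tibble(chrom = ch, pos = cyt$pos, strand = cyt$strand,
                      context = cyt$context, n_meth = n_meth,
                      n_unmeth = depth - n_meth))
      }
      tes <- features[features$chrom == ch, , drop = FALSE]
      cyt$compartment <- compartment_of(cyt$pos, tes)
      cyt <- left_join(cyt, mp, by = c("context", "compartment"))
      n_meth <- rbetabinom(nrow(cyt), cyt$depth, cyt$mean, cyt$overdispersion)
      tibble(chrom = ch, pos = cyt$pos, strand = cyt$strand,
             context = cyt$context, n_meth = n_meth,
             n_unmeth = cyt$depth - n_meth)
    })
  })
}

#' Simulate bisulfite reads with conversion failures
#'
#' Generates per-read methylation call strings over a fixed number of CHH
#' sites (optionally with interleaved CG calls, to exercise the rule that
#' consecutiveness of CHH calls ignores other contexts). A conversion-failed
#' read has every CHH call methylated; a converted read has independent
#' per-site methylation at `true_chh_rate`. The generating label is retained
#' so the unconverted-read filter can be validated against truth.
#'
#' @param n_reads Number of reads (>= 0).
#' @param chh_sites_per_read CHH sites per read.
#' @param failure_rate Probability that a read failed conversion, in `[0, 1]`.
#' @param seed Integer seed.
#' @param true_chh_rate True per-site CHH methylation rate of converted reads.
#' @param n_cg_sites CG sites interleaved at random positions (methylated at
#'   rate 0.8, the typical CG level).
#' @return Tibble: `read_id`, `calls` (Bismark-style string, see
#'   [is_unconverted()]), `failed` (logical truth label).
#' @export
simulate_reads_with_conversion_failure <- function(n_reads, chh_sites_per_read,
                                                   failure_rate, seed = 1L,
                                                   true_chh_rate = 0.1,
                                                   n_cg_sites = 0) {
  if (!is.numeric(failure_rate) || failure_rate < 0 || failure_rate > 1) {
    stop_config("`failure_rate` must lie in [0, 1]")
  }
  if (n_reads < 0) stop_config("`n_reads` must be >= 0")
  withr::with_seed(as.integer(seed), {
    failed <- runif(n_reads) < failure_rate
    calls <- vapply(seq_len(n_reads), function(i) {
      chh <- if (failed[i]) rep(TRUE, chh_sites_per_read)
             else runif(chh_sites_per_read) < true_chh_rate
      sym <- ifelse(chh, "H", "h")
      if (n_cg_sites > 0) {
        cg <- ifelse(runif(n_cg_sites) < 0.8, "Z", "z")
        all_sym <- c(sym, cg)
        ord <- sample.int(length(all_sym))
        sym <- all_sym[ord]
      }
      paste(sym, collapse = "")
    }, character(1))
    tibble(read_id = sprintf("read%05d", seq_len(n_reads)),
           calls = if (n_reads) calls else character(0),
           failed = failed)
  })
}
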