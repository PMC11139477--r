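# Run-length encode a per-base numeric vector into a bedGraph-style tibble.
rle_track <- function(chrom, values) {
  r <- rle(values)
  ends <- cumsum(r$lengths)
  tibble(chrom = chrom, start = c(0, head(ends, -1)), end = ends, value = r$values)
}

# Per-base expected occupancy for one chromosome under the generator model:
# background + edge term inside TEs (amplitude * exp(-d/decay), d = distance
# to the nearest TE edge) + flat body gain across heterochromatic TE bodies
# when body_gain > 0.
expected_signal_chrom <- function(len, tes, pars) {
  mu <- rep(pars$background, len)
  if (nrow(tes) > 0 && pars$edge_amplitude != 0) {
    for (i in seq_len(nrow(tes))) {
      p <- seq(tes$start[i], tes$end[i] - 1)
      d <- pmin(p - tes$start[i], tes$end[i] - 1 - p)
      mu[p + 1] <- mu[p + 1] + pars$edge_amplitude * exp(-d / pars$edge_decay)
    }
  }
  if (pars$body_gain != 0) {
    het <- tes[tes$class == "heterochromatic", , drop = FALSE]
    for (i in seq_len(nrow(het))) {
      idx <- seq(het$start[i] + 1, het$end[i])
      mu[idx] <- mu[idx] + pars$body_gain
    }
  }
  mu
}

chip_pars_for <- function(config, genotype) {
  cp <- config$chip_params
  row <- cp[cp$genotype == genotype, , drop = FALSE]
  if (nrow(row) != 1) {
    stop_config("no chip_params entry for genotype '%s' (available: %s)",
                genotype, paste(cp$genotype, collapse = ", "))
  }
  as.list(row)
}

#' Deterministic expected occupancy surface
#'
#' The noise-free mean of the occupancy model that [simulate_chip_track()]
#' draws from: flat background, TE-edge enrichment decaying exponentially into
#' TE bodies, and (for genotypes with `body_gain > 0`, i.e. `h1`) a flat gain
#' across heterochromatic TE bodies. Useful for model-level checks and as the
#' reference for parameter-recovery tests.
#'
#' @inheritParams simulate_chip_track
#' @return A coverage track tibble (`chrom`, `start`, `end`, `value`),
#'   run-length compressed, 0-based half-open.
#' @export
chip_expected_signal <- function(genome, features, genotype, config) {
  gm <- as_genome_model(genome)
  pars <- chip_pars_for(config, genotype)
  chroms <- gm$chromosomes[is.na(gm$control_contig) |
                             gm$chromosomes$chrom != gm$control_contig, , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(chroms)), function(i) {
    tes <- features[features$chrom == chroms$chrom[i], , drop = FALSE]
    rle_track(chroms$chrom[i],
              expected_signal_chrom(chroms$length[i], tes, pars))
  })
}

#' Simulate an occupancy (ChIP-like) coverage track
#'
#' Draws per-base counts from a Poisson distribution whose mean is the
#' genotype's expected occupancy surface (see [chip_expected_signal()]):
#' background everywhere, edge enrichment at TE boundaries in every ChIP
#' genotype, and heterochromatic TE-body invasion in `h1`. The `input`
#' genotype is background-only and stands in for the sequencing input
#' control. Deterministic under the configuration seed, with a separate
#' substream per genotype.
#'
#' @param genome A `sim_genome` or `genome_model`.
#' @param features TE feature tibble from [place_tes()].
#' @param genotype A genotype present in `config$chip_params` (default table:
#'   `WT`, `h1`, `input`).
#' @param config The [sim_config()].
#' @return A coverage track tibble (`chrom`, `start`, `end`, `value`),
#'   run-length compressed, 0-based half-open.
#' @export
simulate_chip_track <- function(genome, features, genotype, config) {
  validate_sim_config(config)
  gm <- as_genome_model(genome)
  pars <- chip_pars_for(config, genotype)
  chroms <- gm$chromosomes[is.na(gm$control_contig) |
                             gm$chromosomes$chrom != gm$control_contig, , drop = FALSE]
  withr::with_seed(substream_seed(config$seed, paste0("chip_", genotype)), {
    purrr::map_dfr(seq_len(nrow(chroms)), function(i) {
      tes <- features[features$chrom == chroms$chrom[i], , drop = FALSE]
      mu <- expected_signal_chrom(chroms$length[i], tes, pars)
      rle_track(chroms$chrom[i], as.double(rpois(length(mu), mu)))
    })
  })
}
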