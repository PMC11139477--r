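#' Default methylome parameters for the synthetic genotypes
#'
#' One row per genotype x cytosine context x chromatin compartment, giving the
#' mean methylation fraction, the beta-binomial overdispersion, and the
#' per-cytosine sequencing depth used by [simulate_methylome()]. Compartments
#' are `"heterochromatic"` (long pericentromeric TE bodies), `"euchromatic"`
#' (short arm TE bodies) and `"background"` (everything else).
#'
#' The default means encode the qualitative redistribution phenotype the
#' package is built to recover: loss of the linker histone H1 causes large CG
#' and CHG gains over heterochromatic TEs that do not require Pol V (`nrpe1`),
#' while euchromatic CHH methylation depends on Pol V and collapses in
#' `nrpe1`; the `h1_nrpe1` double mutant keeps the heterochromatic CG/CHG
#' gains but loses the CHH gains, and shows a CHG gain at euchromatic TEs
#' relative to `nrpe1` alone.
#'
#' @return A tibble with columns `genotype`, `context`, `compartment`,
#'   `mean`, `overdispersion`, `depth`.
#' @export
default_meth_params <- function() {
  row <- function(genotype, compartment, cg, chg, chh) {
    tibble(
      genotype = genotype, context = c("CG", "CHG", "CHH"),
      compartment = compartment, mean = c(cg, chg, chh),
      overdispersion = 0.1, depth = 30L
    )
  }
  bind_rows(
    row("WT", "heterochromatic", 0.85, 0.65, 0.12),
    row("WT", "euchromatic", 0.50, 0.30, 0.12),
    row("WT", "background", 0.05, 0.03, 0.02),
    row("h1", "heterochromatic", 0.95, 0.85, 0.22),
    row("h1", "euchromatic", 0.50, 0.30, 0.08),
    row("h1", "background", 0.05, 0.03, 0.02),
    row("nrpe1", "heterochromatic", 0.85, 0.65, 0.10),
    row("nrpe1", "euchromatic", 0.50, 0.25, 0.02),
    row("nrpe1", "background", 0.05, 0.03, 0.01),
    row("h1_nrpe1", "heterochromatic", 0.95, 0.85, 0.12),
    row("h1_nrpe1", "euchromatic", 0.50, 0.40, 0.02),
    row("h1_nrpe1", "background", 0.05, 0.03, 0.01)
  )
}

#' Default occupancy-track parameters for the synthetic genotypes
#'
#' Per genotype: flat background level, TE-edge enrichment amplitude, the
#' exponential decay length of the edge term (bp, measured into the TE body),
#' and the extra flat gain across heterochromatic TE bodies. The `"WT"` track
#' has edge enrichment only (the canonical Pol V pattern: short TEs and long-TE
#' edges); `"h1"` adds the heterochromatic body gain (Pol V invading long-TE
#' bodies); `"input"` is background-only and serves as the ChIP input control.
#'
#' @return A tibble with columns `genotype`, `background`, `edge_amplitude`,
#'   `edge_decay`, `body_gain`.
#' @export
default_chip_params <- function() {
  tibble(
    genotype = c("WT", "h1", "input"),
    background = 1,
    edge_amplitude = c(4, 4, 0),
    edge_decay = 150,
    body_gain = c(0, 8, 0)
  )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator: genome geometry,
#' transposable-element placement, per-genotype methylome and occupancy-track
#' parameters, the bisulfite conversion-failure rate, and the global seed from
#' which each generator derives its own deterministic substream.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome, bp.
#' @param pericentromere_fraction Fraction of each chromosome, centered, that
#'   is pericentromeric heterochromatin.
#' @param n_short_te,n_long_te Number of short (euchromatic, arm) and long
#'   (heterochromatic, pericentromeric) TEs to place genome-wide.
#' @param short_te_length,long_te_length Length ranges `c(min, max)` in bp;
#'   the long minimum must exceed the short maximum so length class separates
#'   the compartments.
#' @param meth_params Methylome parameter table, see [default_meth_params()].
#' @param chip_params Occupancy parameter table, see [default_chip_params()].
#' @param conversion_failure_rate Fraction of bisulfite reads that fail
#'   conversion; also the apparent methylation rate of the unmethylated
#'   control contig.
#' @param control_length Length of the unmethylated control contig, bp.
#' @param seed Integer seed; identical configurations (including the seed)
#'   give byte-identical outputs.
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_chromosomes = 2, chrom_length = 50000)
#' cfg$seed
#' @export
sim_config <- function(n_chromosomes = 3,
                       chrom_length = 200000,
                       pericentromere_fraction = 0.3,
                       n_short_te = 60,
                       n_long_te = 15,
                       short_te_length = c(200, 800),
                       long_te_length = c(2000, 6000),
                       meth_params = default_meth_params(),
                       chip_params = default_chip_params(),
                       conversion_failure_rate = 0.005,
                       control_length = 20000,
                       seed = 1L) {
  cfg <- structure(
    list(
      n_chromosomes = n_chromosomes, chrom_length = chrom_length,
      pericentromere_fraction = pericentromere_fraction,
      n_short_te = n_short_te, n_long_te = n_long_te,
      short_te_length = short_te_length, long_te_length = long_te_length,
      meth_params = meth_params, chip_params = chip_params,
      conversion_failure_rate = conversion_failure_rate,
      control_length = control_length, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  pos_count <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v != floor(v)) {
      stop_config("invalid sim_config: `%s` must be a positive integer, got %s",
                  field, deparse(cfg[[field]]))
    }
  }
  for (f in c("n_chromosomes", "chrom_length", "control_length")) pos_count(f)
  for (f in c("n_short_te", "n_long_te")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != floor(v)) {
      stop_config("invalid sim_config: `%s` must be a non-negative integer", f)
    }
  }
  for (f in c("pericentromere_fraction", "conversion_failure_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop_config("invalid sim_config: `%s` must be a fraction in [0, 1]", f)
    }
  }
  for (f in c("short_te_length", "long_te_length")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 2 || any(is.na(v)) || any(v <= 0) || v[1] > v[2]) {
      stop_config("invalid sim_config: `%s` must be a positive c(min, max) range", f)
    }
  }
  if (min(cfg$long_te_length) <= max(cfg$short_te_length)) {
    stop_config(paste0("invalid sim_config: `long_te_length` minimum (%d) must exceed ",
                       "`short_te_length` maximum (%d)"),
                min(cfg$long_te_length), max(cfg$short_te_length))
  }
  mp <- cfg$meth_params
  need <- c("genotype", "context", "compartment", "mean", "overdispersion", "depth")
  if (!is.data.frame(mp) || !all(need %in% names(mp))) {
    stop_config("invalid sim_config: `meth_params` must have columns %s",
                paste(need, collapse = ", "))
  }
  if (any(mp$mean < 0 | mp$mean > 1)) {
    stop_config("invalid sim_config: `meth_params` means must lie in [0, 1]")
  }
  if (any(mp$overdispersion < 0 | mp$overdispersion >= 1)) {
    stop_config("invalid sim_config: `meth_params` overdispersion must lie in [0, 1)")
  }
  if (any(mp$depth < 0)) {
    stop_config("invalid sim_config: `meth_params` depth must be non-negative")
  }
  cp <- cfg$chip_params
  need <- c("genotype", "background", "edge_amplitude", "edge_decay", "body_gain")
  if (!is.data.frame(cp) || !all(need %in% names(cp))) {
    stop_config("invalid sim_config: `chip_params` must have columns %s",
                paste(need, collapse = ", "))
  }
  if (any(cp$edge_decay <= 0)) {
    stop_config("invalid sim_config: `chip_params` edge_decay must be positive")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    stop_config("invalid sim_config: `seed` must be a single integer")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosome(s) x %d bp, pericentromere fraction %.2f\n",
              x$n_chromosomes, x$chrom_length, x$pericentromere_fraction))
  cat(sprintf("  TEs: %d short [%d-%d bp] on arms, %d long [%d-%d bp] pericentromeric\n",
              x$n_short_te, x$short_te_length[1], x$short_te_length[2],
              x$n_long_te, x$long_te_length[1], x$long_te_length[2]))
  cat(sprintf("  genotypes (methylome): %s\n",
              paste(unique(x$meth_params$genotype), collapse = ", ")))
  cat(sprintf("  conversion failure rate: %.3f; seed: %d\n",
              x$conversion_failure_rate, x$seed))
  invisible(x)
}
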