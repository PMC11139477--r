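# Small deterministic fixtures shared across tests. Scaled so the whole
# suite stays fast while keeping every programmed contrast recoverable.

tiny_config <- function(seed = 11, ...) {
  sim_config(
    n_chromosomes = 2, chrom_length = 60000,
    n_short_te = 20, n_long_te = 6, long_te_length = c(2000, 4000),
    seed = seed, ...
  )
}

iv <- function(chrom, start, end) tibble::tibble(chrom = chrom, start = start, end = end)

one_chrom_genome <- function(len = 10, chrom = "c1") {
  genome_model(tibble::tibble(chrom = chrom, length = len))
}

# Independent two-sided exact-test oracle for a 2x2 table, by direct
# enumeration of the conditional (hypergeometric) tail: sum the probabilities
# of all tables with margins fixed whose density does not exceed the
# observed one.
fisher2_oracle <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; K <- a + c
  support <- max(0, K - n2):min(K, n1)
  dens <- dhyper(support, K, n1 + n2 - K, n1)
  dobs <- dhyper(a, K, n1 + n2 - K, n1)
  sum(dens[dens <= dobs * (1 + 1e-7)])
}
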