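#' Genome model: the coordinate universe for all statistics
#'
#' Holds the chromosome names and lengths, one centered pericentromere
#' interval per chromosome (0-based, half-open), and the name of the
#' unmethylated control contig used for conversion-rate estimation. Every
#' overlap null, window tiling and chromosomal profile in the package is
#' defined against this object.
#'
#' @param chromosomes Tibble with columns `chrom`, `length` (bp); order is
#'   preserved.
#' @param pericentromeres Tibble with columns `chrom`, `start`, `end`; one row
#'   per chromosome, each interval contained in its chromosome. May be empty
#'   for genomes without a heterochromatic compartment.
#' @param control_contig Name of the unmethylated spike contig, or `NA` when
#'   absent.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes,
                         pericentromeres = tibble(chrom = character(),
                                                  start = double(), end = double()),
                         control_contig = NA_character_) {
  chromosomes <- as_tibble(chromosomes)
  pericentromeres <- as_tibble(pericentromeres)
  if (!all(c("chrom", "length") %in% names(chromosomes))) {
    stop_input("`chromosomes` needs columns chrom and length")
  }
  if (any(chromosomes$length <= 0)) {
    stop_input("chromosome lengths must be positive")
  }
  if (nrow(pericentromeres) > 0) {
    check_intervals(pericentromeres, "pericentromeres")
    len <- setNames(chromosomes$length, chromosomes$chrom)
    if (any(!pericentromeres$chrom %in% chromosomes$chrom) ||
        any(pericentromeres$start < 0) ||
        any(pericentromeres$end > len[pericentromeres$chrom])) {
      stop_input("pericentromere intervals must be contained in their chromosomes")
    }
  }
  structure(
    list(chromosomes = chromosomes, pericentromeres = pericentromeres,
         control_contig = control_contig),
    class = "genome_model"
  )
}

#' Coerce to a genome model
#'
#' Accepts a `genome_model`, or a simulated genome as returned by
#' [make_genome()] (from which the model is extracted).
#'
#' @param x Object to coerce.
#' @return A `genome_model`.
#' @export
as_genome_model <- function(x) {
  if (inherits(x, "genome_model")) return(x)
  if (inherits(x, "sim_genome")) return(x$model)
  stop_input("cannot interpret object of class <%s> as a genome model",
             paste(class(x), collapse = "/"))
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chromosome(s), %s bp total\n",
              nrow(x$chromosomes), format(sum(x$chromosomes$length), big.mark = ",")))
  if (nrow(x$pericentromeres) > 0) {
    cat(sprintf("  pericentromeres: %s bp total\n",
                format(sum(x$pericentromeres$end - x$pericentromeres$start),
                       big.mark = ",")))
  }
  if (!is.na(x$control_contig)) {
    cat(sprintf("  control contig: %s\n", x$control_contig))
  }
  invisible(x)
}

#' Simulate a multi-chromosome genome with pericentromeres
#'
#' Draws uniform random sequence over A/C/G/T for each chromosome and for an
#' unmethylated control contig, and defines the pericentromere of each
#' chromosome as its central `pericentromere_fraction`. Identical
#' configurations (including the seed) produce byte-identical sequences.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_genome`: a list with `model` (a
#'   [genome_model()]) and `seq` (named character vector of chromosome
#'   sequences, control contig included).
#' @examples
#' g <- make_genome(sim_config(n_chromosomes = 2, chrom_length = 10000))
#' g$model$pericentromeres
#' @export
make_genome <- function(config) {
  validate_sim_config(config)
  n <- config$n_chromosomes
  L <- as.integer(config$chrom_length)
  chroms <- paste0("chr", seq_len(n))
  control <- "ctrl"
  seqs <- withr::with_seed(substream_seed(config$seed, "genome"), {
    lens <- c(rep(L, n), as.integer(config$control_length))
    vapply(lens, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
    }, character(1))
  })
  names(seqs) <- c(chroms, control)
  f <- config$pericentromere_fraction
  pc_start <- floor(L * (1 - f) / 2)
  pc <- tibble(chrom = chroms, start = pc_start, end = pc_start + round(L * f))
  if (f == 0) pc <- pc[0, ]
  structure(
    list(
      model = genome_model(
        chromosomes = tibble(chrom = names(seqs), length = nchar(seqs)),
        pericentromeres = pc,
        control_contig = control
      ),
      seq = seqs
    ),
    class = "sim_genome"
  )
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome>\n")
  print(x$model)
  invisible(x)
}

# Draw `n` non-overlapping intervals (>= 1 bp apart) with lengths sampled
# uniformly from len_range, inside the union of `space` intervals on one
# chromosome scaffold. Free space is updated after each placement, so the
# sampler only fails when no remaining free block can hold the next length.
place_in_space <- function(n, len_range, space) {
  placed <- tibble(chrom = character(), start = double(), end = double())
  if (n == 0) return(placed)
  free <- space[, c("chrom", "start", "end")]
  for (i in seq_len(n)) {
    len <- if (len_range[1] == len_range[2]) len_range[1] else
      sample(seq(len_range[1], len_range[2]), 1)
    cand <- which(free$end - free$start >= len)
    if (length(cand) == 0) {
      abort(
        sprintf("could not place %d features without overlap: achieved %d of %d",
                n, nrow(placed), n),
        class = "methredist_placement_error"
      )
    }
    w <- free$end[cand] - free$start[cand] - len + 1
    j <- cand[sample.int(length(cand), 1, prob = w)]
    s <- free$start[j] + floor(runif(1, 0, free$end[j] - free$start[j] - len + 1))
    e <- s + len
    placed <- bind_rows(placed, tibble(chrom = free$chrom[j], start = s, end = e))
    # split the free block, keeping a 1 bp guard gap around the placement
    left <- tibble(chrom = free$chrom[j], start = free$start[j], end = s - 1)
    right <- tibble(chrom = free$chrom[j], start = e + 1, end = free$end[j])
    free <- bind_rows(free[-j, , drop = FALSE],
                      left[left$end > left$start, ],
                      right[right$end > right$start, ])
  }
  placed
}

#' Place synthetic transposable elements
#'
#' Long TEs are placed non-overlapping inside the pericentromeres and labeled
#' `heterochromatic`; short TEs are placed on the chromosome arms (zero
#' overlap with pericentromeres) and labeled `euchromatic`. Each TE records
#' its chromatin class and length class, the two attributes all downstream
#' contrasts are built on. Placement is uniform within the allowed space with
#' at least 1 bp between neighbours; if the requested number cannot be placed
#' without overlap a placement error reports the achieved count.
#'
#' @param genome A `sim_genome` or `genome_model`.
#' @param config The [sim_config()] used to build the genome.
#' @return A feature tibble: `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `class` (`heterochromatic`/`euchromatic`), `lenclass`
#'   (`long`/`short`).
#' @export
place_tes <- function(genome, config) {
  validate_sim_config(config)
  gm <- as_genome_model(genome)
  chroms <- gm$chromosomes[gm$chromosomes$chrom != gm$control_contig |
                             is.na(gm$control_contig), , drop = FALSE]
  pc <- gm$pericentromeres
  arms <- bind_rows(
    tibble(chrom = pc$chrom, start = 0, end = pc$start),
    tibble(chrom = pc$chrom,
           start = pc$end,
           end = setNames(chroms$length, chroms$chrom)[pc$chrom])
  )
  arms <- arms[arms$end > arms$start, , drop = FALSE]
  withr::with_seed(substream_seed(config$seed, "tes"), {
    long <- place_in_space(config$n_long_te, config$long_te_length, pc)
    short <- place_in_space(config$n_short_te, config$short_te_length, arms)
    strands <- sample(c("+", "-"), nrow(long) + nrow(short), replace = TRUE)
    tes <- bind_rows(
      mutate(long, class = "heterochromatic", lenclass = "long"),
      mutate(short, class = "euchromatic", lenclass = "short")
    )
    tes |>
      mutate(strand = strands, score = 0) |>
      sort_intervals() |>
      mutate(name = sprintf("TE%03d", row_number())) |>
      select("chrom", "start", "end", "name", "score", "strand", "class", "lenclass")
  })
}
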