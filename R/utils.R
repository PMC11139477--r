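# Internal helpers shared across modules. All genomic intervals in this
# package are 0-based, half-open [start, end), BED-style.

# Deterministic child seed for a named random substream. Keeps the value a
# valid 32-bit integer so set.seed() accepts it on any platform.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "methredist_config_error")
}

stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "methredist_input_error")
}

stop_parse <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "methredist_parse_error")
}

check_intervals <- function(x, what = "interval set") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    stop_input("%s must be a data frame with chrom/start/end columns", what)
  }
  if (nrow(x) > 0 && any(x$end <= x$start)) {
    bad <- which(x$end <= x$start)[1]
    stop_input("%s has a malformed interval (end <= start) at row %d", what, bad)
  }
  invisible(x)
}

sort_intervals <- function(x) {
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

# Assign transitive overlap-cluster ids to sorted intervals (>=1 bp overlap;
# half-open touching does not connect). `gap` relaxes the rule so intervals
# with start - prev_end <= gap also connect (gap = -1 reproduces pure overlap).
overlap_clusters <- function(x, gap = -1L) {
  if (nrow(x) == 0) return(integer(0))
  cl <- integer(nrow(x))
  out <- unlist(lapply(split(seq_len(nrow(x)), x$chrom), function(idx) {
    s <- x$start[idx]; e <- x$end[idx]
    k <- integer(length(idx))
    k[1] <- 1L
    if (length(idx) > 1) {
      run_end <- e[1]
      for (i in 2:length(idx)) {
        if (s[i] - run_end <= gap) {
          k[i] <- k[i - 1]
          run_end <- max(run_end, e[i])
        } else {
          k[i] <- k[i - 1] + 1L
          run_end <- e[i]
        }
      }
    }
    k
  }), use.names = FALSE)
  # make ids unique across chromosomes
  chrom_f <- as.integer(factor(x$chrom, levels = unique(x$chrom)))
  out + chrom_f * (nrow(x) + 1L)
}

# Coalesce a set of intervals into their union, honouring a merge gap.
union_intervals <- function(x, gap = -1L) {
  x <- sort_intervals(x)
  if (nrow(x) == 0) return(tibble(chrom = character(), start = double(), end = double()))
  x$.cl <- overlap_clusters(x, gap = gap)
  x |>
    group_by(.data$chrom, .data$.cl) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    select("chrom", "start", "end") |>
    sort_intervals()
}

genome_chrom_lengths <- function(genome) {
  gm <- as_genome_model(genome)
  setNames(gm$chromosomes$length, gm$chromosomes$chrom)
}
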