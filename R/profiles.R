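# Per-base value vector over [start, end) from a run-length track.
# Bases without coverage are NA (distinguishing "no data" from zero signal
# is left to the caller; generator tracks cover every base).
track_values_over <- function(track, chrom, start, end) {
  seg <- track[track$chrom == chrom & track$end > start & track$start < end, ,
               drop = FALSE]
  out <- rep(NA_real_, end - start)
  for (i in seq_len(nrow(seg))) {
    s <- max(seg$start[i], start)
    e <- min(seg$end[i], end)
    out[(s - start + 1):(e - start)] <- seg$value[i]
  }
  out
}

is_cytosine_report <- function(x) {
  is.data.frame(x) && all(c("pos", "n_meth", "n_unmeth") %in% names(x))
}

# Per-base (meth, total) count vectors over [start, end) from a cytosine
# report (already filtered to one context).
meth_counts_over <- function(report, chrom, start, end) {
  seg <- report[report$chrom == chrom & report$pos >= start & report$pos < end, ,
                drop = FALSE]
  meth <- tot <- rep(0, end - start)
  if (nrow(seg) > 0) {
    i <- seg$pos - start + 1
    meth[i] <- meth[i] + seg$n_meth
    tot[i] <- tot[i] + seg$n_meth + seg$n_unmeth
  }
  list(meth = meth, tot = tot)
}

# Mean of per-base values within n bins; values shorter than n are linearly
# interpolated onto n points instead of dropped. All-NA bins give NA.
bin_means <- function(values, n) {
  L <- length(values)
  if (L == 0) return(rep(NA_real_, n))
  if (L < n) {
    if (all(is.na(values))) return(rep(NA_real_, n))
    if (L == 1) return(rep(values, n))
    return(stats::approx(seq_len(L), values, n = n, rule = 2)$y)
  }
  bin <- floor((seq_len(L) - 1) * n / L) + 1
  out <- rep(NA_real_, n)
  means <- tapply(values, bin, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  out[as.integer(names(means))] <- as.numeric(means)
  out
}

# Depth-pooled binned levels for methylation count vectors.
bin_pooled_levels <- function(meth, tot, n) {
  L <- length(tot)
  if (L == 0) return(rep(NA_real_, n))
  if (L < n) {
    lev <- ifelse(tot > 0, meth / tot, NA_real_)
    return(bin_means(lev, n))
  }
  bin <- floor((seq_len(L) - 1) * n / L) + 1
  m <- tapply(meth, bin, sum)
  t <- tapply(tot, bin, sum)
  out <- rep(NA_real_, n)
  out[as.integer(names(m))] <- ifelse(t > 0, m / t, NA_real_)
  out
}

#' Metaprofile over a feature set (flank + scaled body)
#'
#' Computes the average signal profile over features: fixed-width flank bins
#' upstream and downstream, and a body rescaled to a common number of bins
#' per feature (mean within bin; features shorter than the bin count
#' contribute through linear interpolation rather than being dropped). For a
#' coverage track the signal is the per-base value; for a cytosine report
#' it is the depth-pooled methylation level per bin, restricted to
#' `context`. With `strand_aware = TRUE` the bin order of minus-strand
#' features is reversed. The profile is the per-bin mean over features,
#' ignoring features missing in that bin.
#'
#' @param x A coverage track tibble or a cytosine report tibble.
#' @param features Feature tibble (`chrom`, `start`, `end`, optionally
#'   `strand`); must be non-empty.
#' @param flank Flank width on each side, bp (>= 0).
#' @param n_body_bins,n_flank_bins Bin counts for the scaled body and each
#'   flank.
#' @param strand_aware Reverse bin order for `-` features.
#' @param context Context filter, used when `x` is a cytosine report.
#' @return An object of class `metaprofile`: a tibble with `bin` (1-based
#'   across the full profile), `segment` (`upstream`/`body`/`downstream`),
#'   `mean_signal` and `n_features` (features contributing to the bin);
#'   parameters as attribute `params`.
#' @export
metaprofile <- function(x, features, flank = 1000, n_body_bins = 20,
                        n_flank_bins = 10, strand_aware = FALSE,
                        context = NULL) {
  if (nrow(features) == 0) stop_input("`features` must be non-empty")
  if (flank < 0) stop_input("`flank` must be >= 0")
  check_intervals(features, "features")
  use_meth <- is_cytosine_report(x)
  if (use_meth && !is.null(context)) {
    check_context(context)
    x <- x[x$context %in% context, , drop = FALSE]
  }
  n_flank_bins <- if (flank > 0) n_flank_bins else 0
  total_bins <- n_body_bins + 2 * n_flank_bins
  per_feature <- purrr::map(seq_len(nrow(features)), function(i) {
    ch <- features$chrom[i]; s <- features$start[i]; e <- features$end[i]
    prof <- if (use_meth) {
      up <- if (flank > 0) {
        cc <- meth_counts_over(x, ch, s - flank, s)
        bin_pooled_levels(cc$meth, cc$tot, n_flank_bins)
      }
      bd <- {
        cc <- meth_counts_over(x, ch, s, e)
        bin_pooled_levels(cc$meth, cc$tot, n_body_bins)
      }
      dn <- if (flank > 0) {
        cc <- meth_counts_over(x, ch, e, e + flank)
        bin_pooled_levels(cc$meth, cc$tot, n_flank_bins)
      }
      c(up, bd, dn)
    } else {
      up <- if (flank > 0) bin_means(track_values_over(x, ch, s - flank, s), n_flank_bins)
      bd <- bin_means(track_values_over(x, ch, s, e), n_body_bins)
      dn <- if (flank > 0) bin_means(track_values_over(x, ch, e, e + flank), n_flank_bins)
      c(up, bd, dn)
    }
    if (strand_aware && "strand" %in% names(features) && features$strand[i] == "-") {
      prof <- rev(prof)
    }
    prof
  })
  mat <- do.call(rbind, per_feature)
  segment <- c(rep("upstream", n_flank_bins), rep("body", n_body_bins),
               rep("downstream", n_flank_bins))
  out <- tibble(
    bin = seq_len(total_bins),
    segment = segment,
    mean_signal = apply(mat, 2, function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }),
    n_features = apply(mat, 2, function(v) sum(!is.na(v)))
  )
  structure(out, class = c("metaprofile", class(out)),
            params = list(flank = flank, n_body_bins = n_body_bins,
                          n_flank_bins = n_flank_bins,
                          strand_aware = strand_aware, context = context,
                          signal = if (use_meth) "methylation" else "track"))
}

#' Per-feature mean enrichment
#'
#' Width-weighted mean of a coverage track over each feature's span; features
#' with no covered positions are reported as missing, never 0.
#'
#' @param track Coverage track tibble.
#' @param features Feature tibble; extra columns (classes, names) are
#'   carried through.
#' @return The feature tibble with `length` and `mean_signal` columns added.
#' @export
per_feature_enrichment <- function(track, features) {
  check_intervals(features, "features")
  track <- check_track(track)
  features$length <- features$end - features$start
  features$mean_signal <- purrr::map_dbl(seq_len(nrow(features)), function(i) {
    seg <- track[track$chrom == features$chrom[i] &
                   track$end > features$start[i] &
                   track$start < features$end[i], , drop = FALSE]
    if (nrow(seg) == 0) return(NA_real_)
    w <- pmin(seg$end, features$end[i]) - pmax(seg$start, features$start[i])
    sum(seg$value * w) / sum(w)
  })
  as_tibble(features)
}

#' Pairwise class comparison of per-feature summaries
#'
#' Rank-sum tests ([rank_sum_test()]) between every pair of classes of a
#' per-feature summary, with the sign of the median difference. Classes with
#' no non-missing members are excluded with a warning.
#'
#' @param summary A per-feature tibble (e.g. from
#'   [per_feature_enrichment()]).
#' @param class_field Name of the class column.
#' @param value_field Name of the value column (default `mean_signal`).
#' @param alternative Passed to [rank_sum_test()].
#' @return Tibble with one row per class pair: `class_a`, `class_b`, `n_a`,
#'   `n_b`, `median_a`, `median_b`, `direction` (sign of
#'   `median_a - median_b`), `p_value`, `exact`.
#' @export
class_comparison <- function(summary, class_field, value_field = "mean_signal",
                             alternative = "two.sided") {
  if (!class_field %in% names(summary)) {
    stop_input("class column '%s' not found", class_field)
  }
  if (!value_field %in% names(summary)) {
    stop_input("value column '%s' not found", value_field)
  }
  vals <- split(summary[[value_field]], summary[[class_field]])
  vals <- lapply(vals, function(v) v[!is.na(v)])
  empty <- names(vals)[vapply(vals, length, integer(1)) == 0]
  if (length(empty) > 0) {
    warn(sprintf("excluding class(es) with no members: %s",
                 paste(empty, collapse = ", ")))
    vals <- vals[!names(vals) %in% empty]
  }
  if (length(vals) < 2) stop_input("need at least two non-empty classes")
  pairs <- combn(names(vals), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    test <- rank_sum_test(vals[[a]], vals[[b]], alternative = alternative)
    md <- median(vals[[a]]) - median(vals[[b]])
    tibble(class_a = a, class_b = b,
           n_a = length(vals[[a]]), n_b = length(vals[[b]]),
           median_a = median(vals[[a]]), median_b = median(vals[[b]]),
           direction = sign(md), p_value = test$p_value, exact = test$exact)
  })
}

# Depth-pooled methylation level of one report over each feature span.
feature_methylation <- function(report, features, context) {
  check_context(context)
  rep_c <- report[report$context == context, , drop = FALSE]
  purrr::map_dbl(seq_len(nrow(features)), function(i) {
    seg <- rep_c[rep_c$chrom == features$chrom[i] &
                   rep_c$pos >= features$start[i] &
                   rep_c$pos < features$end[i], , drop = FALSE]
    if (nrow(seg) == 0) return(NA_real_)
    methylation_level(sum(seg$n_meth), sum(seg$n_unmeth))
  })
}

#' Per-feature methylation differences between two methylomes
#'
#' For each feature, the depth-pooled methylation level in report A minus
#' that in report B (one context). Features with no covered cytosines in
#' either report are flagged missing. The output is the substrate for
#' kernel-density views of which features gain or lose methylation.
#'
#' @param report_a,report_b Cytosine report tibbles on the same genome.
#' @param features Feature tibble; extra columns carried through.
#' @param context Single context.
#' @return The feature tibble with `level_a`, `level_b` and `diff` columns.
#' @export
methylation_difference_density <- function(report_a, report_b, features, context) {
  check_intervals(features, "features")
  features <- as_tibble(features)
  features$level_a <- feature_methylation(report_a, features, context)
  features$level_b <- feature_methylation(report_b, features, context)
  features$diff <- features$level_a - features$level_b
  features
}

#' Chromosomal window profile with pericentromere annotation
#'
#' Tiling-window summary across each chromosome: windowed means for a
#' coverage track, or depth-pooled methylation per context for a cytosine
#' report (via [window_methylation()]). Each window is labeled
#' `pericentromere` or `arm` by its midpoint (half-open rule: a midpoint
#' exactly at the pericentromere start is pericentromeric). The control
#' contig, when the genome has one, is excluded.
#'
#' @param x Coverage track or cytosine report tibble.
#' @param genome A `genome_model` or `sim_genome`.
#' @param window Window width, bp (default 10,000).
#' @param context Context filter when `x` is a cytosine report.
#' @return Tibble: `chrom`, `start`, `end`, (`context`,) `value`,
#'   `compartment`.
#' @export
chromosomal_profile <- function(x, genome, window = 10000, context = NULL) {
  if (window <= 0) stop_input("`window` must be positive")
  gm <- as_genome_model(genome)
  keep <- is.na(gm$control_contig) | gm$chromosomes$chrom != gm$control_contig
  gm_main <- genome_model(gm$chromosomes[keep, , drop = FALSE],
                          gm$pericentromeres, NA_character_)
  out <- if (is_cytosine_report(x)) {
    window_methylation(x, gm_main, window = window, context = context) |>
      rename(value = "level")
  } else {
    window_means(check_track(x), gm_main, window) |>
      rename(value = "mean")
  }
  pc <- gm$pericentromeres
  mid <- (out$start + out$end) / 2
  out$compartment <- "arm"
  for (i in seq_len(nrow(pc))) {
    hit <- out$chrom == pc$chrom[i] & mid >= pc$start[i] & mid < pc$end[i]
    out$compartment[hit] <- "pericentromere"
  }
  out
}
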