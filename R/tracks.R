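#' Total mass of a coverage track
#'
#' Sum of value times span over all runs, the analogue of a library's mapped
#' read count for bedGraph-style tracks.
#'
#' @param track Coverage track tibble (`chrom`, `start`, `end`, `value`).
#' @return A single number.
#' @export
track_mass <- function(track) {
  check_intervals(track, "track")
  sum(track$value * (track$end - track$start))
}

check_track <- function(track, what = "track") {
  check_intervals(track, what)
  if (!"value" %in% names(track)) stop_input("%s needs a `value` column", what)
  if (any(!is.finite(track$value))) stop_input("%s has non-finite values", what)
  t <- sort_intervals(track)
  by_chrom <- split(seq_len(nrow(t)), t$chrom)
  for (idx in by_chrom) {
    if (length(idx) > 1 && any(t$start[idx][-1] < t$end[idx][-length(idx)])) {
      stop_input("%s has overlapping runs", what)
    }
  }
  t
}

# Decompose two tracks onto a common set of breakpoints per chromosome.
# Positions covered by neither run contribute value 0. Returns a tibble with
# chrom/start/end/value_a/value_b.
align_tracks <- function(a, b) {
  chroms <- union(unique(a$chrom), unique(b$chrom))
  purrr::map_dfr(chroms, function(ch) {
    ra <- a[a$chrom == ch, , drop = FALSE]
    rb <- b[b$chrom == ch, , drop = FALSE]
    bp <- sort(unique(c(ra$start, ra$end, rb$start, rb$end)))
    if (length(bp) < 2) return(tibble())
    s <- bp[-length(bp)]
    e <- bp[-1]
    val_at <- function(runs, pos) {
      if (nrow(runs) == 0) return(rep(0, length(pos)))
      i <- findInterval(pos, runs$start)
      ifelse(i > 0 & pos < runs$end[pmax(i, 1)], runs$value[pmax(i, 1)], 0)
    }
    tibble(chrom = ch, start = s, end = e,
           value_a = val_at(ra, s), value_b = val_at(rb, s))
  })
}

# Collapse adjacent runs with identical value back into maximal runs.
compress_runs <- function(track) {
  track |>
    group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      d <- arrange(d, .data$start)
      d$brk <- cumsum(c(TRUE, d$value[-1] != d$value[-nrow(d)] |
                                d$start[-1] != d$end[-nrow(d)]))
      d |>
        group_by(.data$brk) |>
        summarise(start = min(.data$start), end = max(.data$end),
                  value = first(.data$value), .groups = "drop") |>
        select(-"brk")
    }) |>
    ungroup() |>
    select("chrom", "start", "end", "value") |>
    sort_intervals()
}

#' Normalize a ChIP track against its input
#'
#' Scales the two tracks to equal total mass — the larger library is scaled
#' down to the smaller, the read-count scaling convention — and then combines
#' them per base as either `log2((chip + pseudocount) / (input + pseudocount))`
#' or `chip - input`. Output is run-length compressed. Positions covered by
#' neither track are treated as zero signal.
#'
#' @param chip,reference Coverage track tibbles over the same genome.
#' @param method `"log2_ratio"` or `"subtract"`.
#' @param pseudocount Added to both terms in the log2 ratio.
#' @return A normalized coverage track tibble.
#' @export
normalize_track <- function(chip, reference, method = c("log2_ratio", "subtract"),
                            pseudocount = 1) {
  method <- match.arg(method)
  chip <- check_track(chip, "chip")
  reference <- check_track(reference, "reference")
  m_chip <- track_mass(chip)
  m_ref <- track_mass(reference)
  if (m_ref <= 0) stop_input("reference track has zero (or negative) total mass")
  if (m_chip <= 0) stop_input("chip track has zero (or negative) total mass")
  if (m_chip > m_ref) {
    chip$value <- chip$value * (m_ref / m_chip)
  } else {
    reference$value <- reference$value * (m_chip / m_ref)
  }
  al <- align_tracks(chip, reference)
  al$value <- if (method == "log2_ratio") {
    log2((al$value_a + pseudocount) / (al$value_b + pseudocount))
  } else {
    al$value_a - al$value_b
  }
  compress_runs(select(al, "chrom", "start", "end", "value"))
}

#' Call enriched regions on a normalized track
#'
#' Takes the maximal runs whose value meets the threshold, drops runs
#' shorter than `min_width`, and merges surviving runs whose gap is at most
#' `merge_gap` bp.
#'
#' @param track Normalized coverage track tibble.
#' @param threshold Minimum value, finite.
#' @param min_width Minimum run width, bp.
#' @param merge_gap Maximum gap between runs to merge, bp.
#' @return Feature tibble: `chrom`, `start`, `end`, `name`, `score` (mean
#'   value over the peak), `strand` (`"."`).
#' @export
call_enriched_peaks <- function(track, threshold, min_width = 1, merge_gap = 0) {
  if (!is.finite(threshold)) stop_config("`threshold` must be finite")
  track <- check_track(track)
  hot <- track[track$value >= threshold, , drop = FALSE]
  if (nrow(hot) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  name = character(), score = double(), strand = character()))
  }
  # coalesce touching runs first so "maximal runs" ignores value changes
  runs <- union_intervals(select(hot, "chrom", "start", "end"), gap = 0L)
  runs <- runs[runs$end - runs$start >= min_width, , drop = FALSE]
  if (nrow(runs) > 0 && merge_gap > 0) {
    runs <- union_intervals(runs, gap = merge_gap)
  }
  if (nrow(runs) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  name = character(), score = double(), strand = character()))
  }
  runs$score <- purrr::map_dbl(seq_len(nrow(runs)), function(i) {
    seg <- track[track$chrom == runs$chrom[i] &
                   track$end > runs$start[i] & track$start < runs$end[i], , drop = FALSE]
    w <- pmin(seg$end, runs$end[i]) - pmax(seg$start, runs$start[i])
    sum(seg$value * w) / sum(w)
  })
  runs |>
    mutate(name = sprintf("peak%04d", row_number()), strand = ".") |>
    select("chrom", "start", "end", "name", "score", "strand")
}

# Mean signal per tiling window for a run-length track: uncovered bases
# count as zero. Returns the full window grid with a `mean` column.
window_means <- function(track, genome, window) {
  grid <- window_grid(genome, window)
  grid$.w <- seq_len(nrow(grid))
  pieces <- track |>
    mutate(w_first = floor(.data$start / window),
           w_last = floor((.data$end - 1) / window))
  # split runs at window boundaries
  reps <- pieces$w_last - pieces$w_first + 1
  idx <- rep(seq_len(nrow(pieces)), reps)
  w <- pieces$w_first[idx] + sequence(reps) - 1
  ps <- pmax(pieces$start[idx], w * window)
  pe <- pmin(pieces$end[idx], (w + 1) * window)
  contrib <- tibble(chrom = pieces$chrom[idx], win_start = w * window,
                    mass = pieces$value[idx] * (pe - ps)) |>
    group_by(.data$chrom, .data$win_start) |>
    summarise(mass = sum(.data$mass), .groups = "drop")
  grid |>
    left_join(contrib, by = c("chrom", "start" = "win_start")) |>
    mutate(mean = dplyr::coalesce(.data$mass, 0) / (.data$end - .data$start)) |>
    select("chrom", "start", "end", "mean")
}

#' Differential occupancy regions between two tracks
#'
#' A windowed fold-change caller standing in for likelihood-based
#' differential peak callers: the tracks are scaled to equal mass, mean
#' signals `a` and `b` are computed per tiling window, and a window is a
#' gain when `a >= min_signal` and `a / (b + pseudocount) >= min_fold`
#' (loss symmetric). Same-direction windows within `merge_gap` bp are
#' merged. Swapping the arguments exchanges the gain and loss sets exactly.
#'
#' @param track_a,track_b Coverage track tibbles (e.g. mutant vs wild type).
#' @param genome A `genome_model` or `sim_genome`.
#' @param window Window width, bp.
#' @param min_fold Minimum fold change.
#' @param min_signal Minimum windowed mean in the higher sample; defaults to
#'   the 75th percentile of the pooled (both tracks) windowed means.
#' @param merge_gap Merge gap for same-direction windows, bp.
#' @param pseudocount Added to the denominator of the fold.
#' @return A list of class `diff_regions` with elements `gain` and `loss`
#'   (interval tibbles) and the parameters as attribute `params`.
#' @export
differential_regions <- function(track_a, track_b, genome, window = 50,
                                 min_fold = 2, min_signal = NULL,
                                 merge_gap = 100, pseudocount = 1) {
  if (window <= 0 || min_fold <= 0 || merge_gap < 0 || pseudocount < 0) {
    stop_config("invalid parameters: need window > 0, min_fold > 0, merge_gap >= 0, pseudocount >= 0")
  }
  track_a <- check_track(track_a, "track_a")
  track_b <- check_track(track_b, "track_b")
  m_a <- track_mass(track_a)
  m_b <- track_mass(track_b)
  if (m_a <= 0 || m_b <= 0) stop_input("both tracks need positive total mass")
  if (m_a > m_b) track_a$value <- track_a$value * (m_b / m_a)
  else track_b$value <- track_b$value * (m_a / m_b)
  wa <- window_means(track_a, genome, window)
  wb <- window_means(track_b, genome, window)
  stopifnot(nrow(wa) == nrow(wb))
  if (is.null(min_signal)) {
    min_signal <- quantile(c(wa$mean, wb$mean), 0.75, names = FALSE)
  }
  gain_w <- wa$mean >= min_signal & wa$mean / (wb$mean + pseudocount) >= min_fold
  loss_w <- wb$mean >= min_signal & wb$mean / (wa$mean + pseudocount) >= min_fold
  pick <- function(sel) {
    if (!any(sel)) {
      return(tibble(chrom = character(), start = double(), end = double()))
    }
    union_intervals(wa[sel, c("chrom", "start", "end")], gap = merge_gap)
  }
  structure(
    list(gain = pick(gain_w), loss = pick(loss_w)),
    class = "diff_regions",
    params = list(window = window, min_fold = min_fold, min_signal = min_signal,
                  merge_gap = merge_gap, pseudocount = pseudocount)
  )
}

#' @export
print.diff_regions <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<diff_regions> %d gain, %d loss (window %g bp, fold >= %g, signal >= %.3g)\n",
              nrow(x$gain), nrow(x$loss), p$window, p$min_fold, p$min_signal))
  invisible(x)
}

#' @export
glance.diff_regions <- function(x, ...) {
  p <- attr(x, "params")
  tibble(n_gain = nrow(x$gain), n_loss = nrow(x$loss),
         gain_bp = sum(x$gain$end - x$gain$start),
         loss_bp = sum(x$loss$end - x$loss$start),
         window = p$window, min_fold = p$min_fold, min_signal = p$min_signal)
}
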