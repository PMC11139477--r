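# Default minimum level difference per context: CHH changes are smaller in
# absolute terms than CG/CHG changes, so the threshold is halved.
default_min_diff <- function(context) {
  if (context == "CHH") 0.1 else 0.2
}

#' Call differentially methylated regions between two methylomes
#'
#' A transparent windowed exact-test caller. Each chromosome is tiled with
#' fixed-width windows; for every window with at least `min_coverage` total
#' counts in both samples, the pooled counts form a 2x2 table
#' (methylated/unmethylated x sample) tested with a two-sided exact test
#' (conditional on margins). P-values are Benjamini-Hochberg adjusted across
#' all tested windows; windows with `p_adj <= alpha` and an absolute level
#' difference of at least `min_diff` become seeds; adjacent same-direction
#' seeds whose gap is at most `merge_gap` bp are merged, and the merged
#' region's levels and exact-test p-value are recomputed on its pooled
#' counts (`p_adj` is the smallest member-window value, all `<= alpha` by
#' construction). Direction is labeled relative to the first sample:
#' `hyper` means A is more methylated than B.
#'
#' @param report_a,report_b Cytosine report tibbles on the same genome.
#' @param context Single context to call in (`"CG"`, `"CHG"`, `"CHH"`).
#' @param genome A `genome_model` or `sim_genome`.
#' @param window Window width, bp.
#' @param min_coverage Minimum total counts required per window in each
#'   sample for the window to be tested.
#' @param min_diff Minimum absolute pooled-level difference; defaults to
#'   0.1 for CHH and 0.2 for CG/CHG.
#' @param alpha BH-adjusted significance threshold.
#' @param merge_gap Maximum gap (bp) between same-direction seed windows to
#'   merge, matching Homer's `mergePeaks -d` convention.
#' @return A tibble of class `meth_dmr`: `chrom`, `start`, `end`, `context`,
#'   `direction` (`hyper`/`hypo`), `level_a`, `level_b`, `diff`, `p_value`,
#'   `p_adj`, `n_windows`, `n_cytosines`. Calling parameters are attached as
#'   the `params` attribute.
#' @export
call_dmrs <- function(report_a, report_b, context, genome,
                      window = 100, min_coverage = 10,
                      min_diff = default_min_diff(context),
                      alpha = 0.05, merge_gap = 100) {
  check_context(context)
  if (window <= 0 || min_coverage < 0 || min_diff < 0 || min_diff > 1 ||
      alpha <= 0 || alpha > 1 || merge_gap < 0) {
    stop_config("invalid DMR parameters (window > 0, min_coverage >= 0, min_diff in [0,1], alpha in (0,1], merge_gap >= 0)")
  }
  pool_windows <- function(report) {
    report[report$context == context, , drop = FALSE] |>
      mutate(win = floor(.data$pos / window)) |>
      group_by(.data$chrom, .data$win) |>
      summarise(meth = sum(.data$n_meth), unmeth = sum(.data$n_unmeth),
                n_cyt = dplyr::n(), .groups = "drop")
  }
  wa <- pool_windows(report_a)
  wb <- pool_windows(report_b)
  tab <- inner_join(wa, wb, by = c("chrom", "win"), suffix = c("_a", "_b"))
  if (nrow(tab) == 0) {
    stop_input("the two reports share no covered %s windows", context)
  }
  tab <- tab |>
    filter(.data$meth_a + .data$unmeth_a >= min_coverage,
           .data$meth_b + .data$unmeth_b >= min_coverage)
  empty <- tibble(
    chrom = character(), start = double(), end = double(), context = character(),
    direction = character(), level_a = double(), level_b = double(),
    diff = double(), p_value = double(), p_adj = double(),
    n_windows = integer(), n_cytosines = integer()
  )
  params <- list(context = context, window = window, min_coverage = min_coverage,
                 min_diff = min_diff, alpha = alpha, merge_gap = merge_gap)
  if (nrow(tab) == 0) {
    return(structure(empty, class = c("meth_dmr", class(empty)), params = params))
  }
  tab$p_value <- vapply(seq_len(nrow(tab)), function(i) {
    fisher.test(matrix(c(tab$meth_a[i], tab$unmeth_a[i],
                         tab$meth_b[i], tab$unmeth_b[i]), nrow = 2))$p.value
  }, double(1))
  tab$p_adj <- p.adjust(tab$p_value, method = "BH")
  tab <- tab |>
    mutate(level_a = methylation_level(.data$meth_a, .data$unmeth_a),
           level_b = methylation_level(.data$meth_b, .data$unmeth_b),
           diff = .data$level_a - .data$level_b)
  seeds <- tab |>
    filter(.data$p_adj <= alpha, abs(.data$diff) >= min_diff) |>
    mutate(direction = if_else(.data$diff > 0, "hyper", "hypo"),
           start = .data$win * window,
           end = (.data$win + 1) * window) |>
    arrange(.data$chrom, .data$start)
  if (nrow(seeds) == 0) {
    return(structure(empty, class = c("meth_dmr", class(empty)), params = params))
  }
  # merge same-direction seeds within merge_gap, per chromosome
  merged <- seeds |>
    group_by(.data$chrom, .data$direction) |>
    dplyr::group_modify(function(d, key) {
      d <- arrange(d, .data$start)
      gap_break <- c(TRUE, d$start[-1] - d$end[-nrow(d)] > merge_gap)
      d$.grp <- cumsum(gap_break)
      d |>
        group_by(.data$.grp) |>
        summarise(start = min(.data$start), end = max(.data$end),
                  meth_a = sum(.data$meth_a), unmeth_a = sum(.data$unmeth_a),
                  meth_b = sum(.data$meth_b), unmeth_b = sum(.data$unmeth_b),
                  p_adj = min(.data$p_adj),
                  n_windows = dplyr::n(),
                  n_cytosines = as.integer(sum(.data$n_cyt_a)),
                  .groups = "drop") |>
        select(-".grp")
    }) |>
    ungroup()
  merged$p_value <- vapply(seq_len(nrow(merged)), function(i) {
    fisher.test(matrix(c(merged$meth_a[i], merged$unmeth_a[i],
                         merged$meth_b[i], merged$unmeth_b[i]), nrow = 2))$p.value
  }, double(1))
  out <- merged |>
    mutate(context = context,
           level_a = methylation_level(.data$meth_a, .data$unmeth_a),
           level_b = methylation_level(.data$meth_b, .data$unmeth_b),
           diff = .data$level_a - .data$level_b) |>
    select("chrom", "start", "end", "context", "direction", "level_a",
           "level_b", "diff", "p_value", "p_adj", "n_windows", "n_cytosines") |>
    sort_intervals()
  structure(out, class = c("meth_dmr", class(empty)), params = params)
}

#' @export
glance.meth_dmr <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    context = p$context, n_dmrs = nrow(x),
    n_hyper = sum(x$direction == "hyper"), n_hypo = sum(x$direction == "hypo"),
    total_bp = sum(x$end - x$start),
    window = p$window, min_diff = p$min_diff, alpha = p$alpha,
    merge_gap = p$merge_gap
  )
}

#' Merge interval sets with a gap tolerance (Homer mergePeaks-style)
#'
#' Takes one or more interval sets and transitively unions all intervals
#' (across sets) whose gap — start of the later minus end of the earlier,
#' half-open — is at most `max_gap` bp. Each merged interval records which
#' input sets contributed, so co-occurring regions can be read off directly.
#'
#' @param sets A named list of interval tibbles (`chrom`, `start`, `end`).
#' @param max_gap Maximum gap allowed inside a merged interval, bp
#'   (default 100, Homer's `-d 100`).
#' @return Tibble of merged intervals: `chrom`, `start`, `end`, one logical
#'   membership column per input set, and `n_members` (total contributing
#'   intervals).
#' @examples
#' merge_interval_sets(list(
#'   a = tibble::tibble(chrom = "c1", start = 0, end = 50),
#'   b = tibble::tibble(chrom = "c1", start = 120, end = 200)
#' ))
#' @export
merge_interval_sets <- function(sets, max_gap = 100) {
  if (is.data.frame(sets)) sets <- list(set1 = sets)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  purrr::walk2(sets, names(sets), function(s, nm) check_intervals(s, nm))
  all <- purrr::imap_dfr(sets, function(s, nm) {
    tibble(chrom = s$chrom, start = s$start, end = s$end, .set = nm)
  })
  if (nrow(all) == 0) {
    out <- tibble(chrom = character(), start = double(), end = double())
    for (nm in names(sets)) out[[nm]] <- logical(0)
    out$n_members <- integer(0)
    return(out)
  }
  all <- sort_intervals(all)
  all$.cl <- overlap_clusters(all, gap = max_gap)
  merged <- all |>
    group_by(.data$chrom, .data$.cl) |>
    summarise(start = min(.data$start), end = max(.data$end),
              members = list(.data$.set), .groups = "drop")
  for (nm in names(sets)) {
    merged[[nm]] <- purrr::map_lgl(merged$members, ~ nm %in% .x)
  }
  merged |>
    mutate(n_members = purrr::map_int(.data$members, length)) |>
    select("chrom", "start", "end", dplyr::all_of(names(sets)), "n_members") |>
    sort_intervals()
}
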