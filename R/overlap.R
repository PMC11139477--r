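#' Count overlaps between two interval sets
#'
#' The symmetric overlap count used throughout the co-occurrence statistics:
#' the number of connected components of the overlap graph between the two
#' sets, where a component is a maximal run of transitively overlapping
#' intervals (>= 1 bp; half-open touching does not count) that contains at
#' least one interval from each set. This convention mirrors merged-peak
#' semantics and makes the count symmetric in its arguments by construction.
#'
#' @param set_a,set_b Interval tibbles (`chrom`, `start`, `end`).
#' @return A single non-negative integer.
#' @examples
#' a <- tibble::tibble(chrom = "c1", start = c(0, 20), end = c(10, 30))
#' b <- tibble::tibble(chrom = "c1", start = 5, end = 25)
#' count_overlaps(a, b)  # 1: one component spans all three intervals
#' @export
count_overlaps <- function(set_a, set_b) {
  check_intervals(set_a, "set_a")
  check_intervals(set_b, "set_b")
  if (nrow(set_a) == 0 || nrow(set_b) == 0) return(0L)
  count_overlaps_fast(set_a$chrom, set_a$start, set_a$end,
                      set_b$chrom, set_b$start, set_b$end)
}

# Core counting on bare vectors (no validation), reused by the Monte Carlo
# null where it runs tens of thousands of times.
count_overlaps_fast <- function(ca, sa, ea, cb, sb, eb) {
  chrom <- c(ca, cb)
  start <- c(sa, sb)
  end <- c(ea, eb)
  from_a <- c(rep(TRUE, length(sa)), rep(FALSE, length(sb)))
  o <- order(chrom, start, end)
  chrom <- chrom[o]; start <- start[o]; end <- end[o]; from_a <- from_a[o]
  n <- length(start)
  new_cl <- c(TRUE, chrom[-1] != chrom[-n] | start[-1] >= cummax_by(end, chrom))
  cl <- cumsum(new_cl)
  has_a <- rowsum(as.integer(from_a), cl) > 0
  has_b <- rowsum(as.integer(!from_a), cl) > 0
  sum(has_a & has_b)
}

# Running maximum of `end` within chromosome, lagged by one (the value a
# sorted interval must reach to connect to the running cluster).
cummax_by <- function(end, chrom) {
  n <- length(end)
  run_max <- end
  same <- chrom[-1] == chrom[-n]
  for (i in seq_len(n - 1)) {
    if (same[i] && run_max[i] > run_max[i + 1]) run_max[i + 1] <- run_max[i]
  }
  run_max[-n]
}

#' Monte Carlo expected overlap under random placement
#'
#' Estimates the number of overlaps expected "by chance" when regions are
#' randomly distributed throughout the genome: in each permutation every
#' interval of the randomized set is re-placed uniformly at random on its own
#' chromosome (length preserved, fully contained, overlaps among placed
#' intervals allowed) and overlaps with the fixed set are counted. The
#' default randomizes each set in turn and averages the two directions, so
#' the resulting fold is symmetric. The empirical p-value uses the +1
#' correction, `(1 + #(null >= observed)) / (1 + n)`, and never returns 0.
#'
#' @param set_a,set_b Interval tibbles.
#' @param genome A `genome_model` or `sim_genome`.
#' @param n_permutations Permutations per randomized direction (>= 100).
#' @param seed Integer seed for the placement stream.
#' @param randomize Which set to re-place: `"both"` (default), `"a"`, `"b"`.
#' @param alternative `"enrichment"` (upper tail) or `"depletion"`.
#' @return An object of class `overlap_result`: a list with `observed`,
#'   `expected`, `fold`, `p_value`, `null_method = "monte_carlo"`,
#'   `n_permutations`, `alternative` and a `null` summary
#'   (mean, sd, quantiles).
#' @export
expected_overlaps_mc <- function(set_a, set_b, genome, n_permutations = 1000,
                                 seed = 1L, randomize = c("both", "a", "b"),
                                 alternative = c("enrichment", "depletion")) {
  randomize <- match.arg(randomize)
  alternative <- match.arg(alternative)
  if (n_permutations < 100) stop_config("`n_permutations` must be >= 100")
  check_intervals(set_a, "set_a")
  check_intervals(set_b, "set_b")
  lens <- genome_chrom_lengths(genome)
  for (s in list(set_a, set_b)) {
    if (nrow(s) > 0 && any(s$end - s$start > lens[s$chrom])) {
      stop_input("an interval is longer than its chromosome")
    }
  }
  observed <- count_overlaps(set_a, set_b)
  empty <- nrow(set_a) == 0 || nrow(set_b) == 0
  draw_null <- function(moving, fixed, n_perm) {
    max_start <- lens[moving$chrom] - (moving$end - moving$start)
    vapply(seq_len(n_perm), function(i) {
      ns <- floor(runif(nrow(moving), 0, max_start + 1))
      count_overlaps_fast(moving$chrom, ns, ns + (moving$end - moving$start),
                          fixed$chrom, fixed$start, fixed$end)
    }, double(1))
  }
  null <- withr::with_seed(as.integer(seed), {
    if (empty) {
      rep(0, n_permutations)
    } else if (randomize == "a") {
      draw_null(set_a, set_b, n_permutations)
    } else if (randomize == "b") {
      draw_null(set_b, set_a, n_permutations)
    } else {
      c(draw_null(set_a, set_b, n_permutations),
        draw_null(set_b, set_a, n_permutations))
    }
  })
  expected <- mean(null)
  k <- if (alternative == "enrichment") sum(null >= observed) else sum(null <= observed)
  structure(
    list(
      observed = observed,
      expected = expected,
      # expected 0 with both sets non-empty (e.g. disjoint chromosomes) is a
      # true absence of chance overlap: fold 0 when nothing was observed.
      fold = if (expected > 0) observed / expected
             else if (!empty && observed == 0) 0 else NA_real_,
      p_value = (1 + k) / (1 + length(null)),
      null_method = "monte_carlo",
      n_permutations = length(null),
      alternative = alternative,
      null = list(mean = expected, sd = stats::sd(null),
                  q = quantile(null, c(0.025, 0.5, 0.975)))
    ),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result: %s>\n", x$null_method))
  cat(sprintf("  observed %s, expected %.3f, fold %s, p = %.3g (%s)\n",
              format(x$observed), x$expected,
              if (is.na(x$fold)) "NA" else sprintf("%.3f", x$fold),
              x$p_value, x$alternative %||% "enrichment"))
  invisible(x)
}

#' @export
tidy.overlap_result <- function(x, ...) {
  tibble(
    observed = x$observed, expected = x$expected, fold = x$fold,
    p_value = x$p_value, null_method = x$null_method,
    n_permutations = x$n_permutations %||% NA_integer_,
    alternative = x$alternative %||% "enrichment"
  )
}

#' Hypergeometric overlap enrichment on a unit tiling
#'
#' Tiles the genome into fixed-size units, marks a unit for a set when at
#' least 1 bp of the set covers it, and tests the number of doubly marked
#' units against the hypergeometric null: with `N` units of which `n_A` are
#' A-marked and `n_B` B-marked, the expected double count is
#' `n_A * n_B / N` and the upper-tail p-value is `P(X >= x)` for
#' `X ~ Hypergeometric(N, n_A, n_B)`. This is the bin-based peak-set
#' enrichment used for occupancy-change versus chromatin-mark-change
#' comparisons.
#'
#' @param set_a,set_b Interval tibbles.
#' @param genome A `genome_model` or `sim_genome`.
#' @param unit Tile size, bp (default 1000). Must not exceed the smallest
#'   chromosome.
#' @return An object of class `overlap_result` with `null_method =
#'   "hypergeometric"` and fields `n_units`, `n_a`, `n_b` in addition to
#'   `observed`, `expected`, `fold`, `p_value`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, genome, unit = 1000) {
  if (!is.numeric(unit) || length(unit) != 1 || unit <= 0) {
    stop_config("`unit` must be a positive tile size in bp")
  }
  gm <- as_genome_model(genome)
  if (unit > min(gm$chromosomes$length)) {
    stop_config("`unit` (%d bp) exceeds the smallest chromosome (%d bp)",
                unit, min(gm$chromosomes$length))
  }
  check_intervals(set_a, "set_a")
  check_intervals(set_b, "set_b")
  grid <- window_grid(gm, unit)
  mark <- function(set) {
    if (nrow(set) == 0) return(logical(nrow(grid)))
    hit <- rep(FALSE, nrow(grid))
    offsets <- c(0, cumsum(ceiling(gm$chromosomes$length / unit)))
    names(offsets) <- c(gm$chromosomes$chrom, ".end")
    for (i in seq_len(nrow(set))) {
      u <- seq(floor(set$start[i] / unit), floor((set$end[i] - 1) / unit))
      hit[offsets[[set$chrom[i]]] + u + 1] <- TRUE
    }
    hit
  }
  a_mark <- mark(set_a)
  b_mark <- mark(set_b)
  N <- nrow(grid)
  n_a <- sum(a_mark)
  n_b <- sum(b_mark)
  x <- sum(a_mark & b_mark)
  expected <- n_a * n_b / N
  structure(
    list(
      observed = x, expected = expected,
      fold = if (expected > 0) x / expected else NA_real_,
      p_value = phyper(x - 1, n_a, N - n_a, n_b, lower.tail = FALSE),
      null_method = "hypergeometric",
      n_units = N, n_a = n_a, n_b = n_b, unit = unit
    ),
    class = "overlap_result"
  )
}

#' Pairwise co-occurrence similarity matrix of region sets
#'
#' For every pair of named sets, computes the fold of observed overlaps over
#' the Monte Carlo random-placement expectation (see [count_overlaps()] and
#' [expected_overlaps_mc()]; both directions averaged, so the matrix is
#' symmetric). Rows are then hierarchically clustered with average linkage
#' on the correlation distance (1 - Pearson) of the log2 fold rows; labels
#' are put in lexicographic order before clustering so the leaf order is
#' deterministic, ties included. Empty sets get a missing row/column and are
#' left out of the clustering.
#'
#' @param sets Named list of interval tibbles (>= 2).
#' @param genome A `genome_model` or `sim_genome`.
#' @param n_permutations Permutations per direction and pair.
#' @param seed Integer seed.
#' @return An object of class `cooccurrence_matrix`: list with `labels`,
#'   `fold` (matrix), `observed`, `expected`, `p_value` (matrices),
#'   `leaf_order` (labels in clustered display order), `hclust` (or `NULL`
#'   when fewer than 3 non-empty sets) and `n_permutations`.
#' @export
cooccurrence_matrix <- function(sets, genome, n_permutations = 200, seed = 1L) {
  if (length(sets) < 2) stop_input("need at least two region sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop_input("`sets` must be a fully named list")
  }
  labels <- sort(names(sets))
  sets <- sets[labels]
  k <- length(labels)
  fold <- obs <- expd <- pval <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  nonempty <- vapply(sets, nrow, integer(1)) > 0
  if (any(!nonempty)) {
    warn(sprintf("empty set(s) flagged missing: %s",
                 paste(labels[!nonempty], collapse = ", ")))
  }
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (!nonempty[i] || !nonempty[j]) next
      r <- expected_overlaps_mc(sets[[i]], sets[[j]], genome,
                                n_permutations = n_permutations,
                                seed = substream_seed(seed, paste(labels[i], labels[j])))
      obs[i, j] <- obs[j, i] <- r$observed
      expd[i, j] <- expd[j, i] <- r$expected
      fold[i, j] <- fold[j, i] <- r$fold
      pval[i, j] <- pval[j, i] <- r$p_value
    }
  }
  leaf_order <- labels[nonempty]
  hc <- NULL
  if (sum(nonempty) >= 3) {
    lf <- log2(pmax(fold[nonempty, nonempty, drop = FALSE], 2^-6))
    d <- as.dist(1 - stats::cor(t(lf)))
    d[is.na(d)] <- 1
    hc <- hclust(d, method = "average")
    leaf_order <- labels[nonempty][hc$order]
  }
  structure(
    list(labels = labels, fold = fold, observed = obs, expected = expd,
         p_value = pval, leaf_order = leaf_order, hclust = hc,
         linkage = "average linkage on 1 - Pearson correlation of log2 fold rows",
         n_permutations = n_permutations),
    class = "cooccurrence_matrix"
  )
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat(sprintf("<cooccurrence_matrix> %d sets, %d permutations/direction\n",
              length(x$labels), x$n_permutations))
  print(round(x$fold, 2))
  cat("leaf order:", paste(x$leaf_order, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
tidy.cooccurrence_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(x$fold, responseName = "fold",
                                stringsAsFactors = FALSE)) |>
    rename(set_a = "Var1", set_b = "Var2") |>
    mutate(
      observed = as.vector(x$observed),
      expected = as.vector(x$expected),
      p_value = as.vector(x$p_value)
    )
}
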