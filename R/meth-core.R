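#' Assign the cytosine sequence context
#'
#' Implements the standard three-context rule on a given strand: a cytosine
#' followed by G is `CG`; by H then G is `CHG`; by H then H is `CHH`, where
#' H is A, C or T. Minus-strand positions are evaluated on the reverse
#' complement, i.e. a genomic G with the preceding bases read leftwards.
#' Positions whose context cannot be determined because they lie within 2 bp
#' of the 3' end of the readable sequence are reported as `"undetermined"`,
#' never guessed.
#'
#' @param sequence A single DNA string (A/C/G/T).
#' @param pos 0-based position(s) within the sequence.
#' @param strand `"+"` or `"-"`, recycled along `pos`.
#' @return Character vector along `pos`: `"CG"`, `"CHG"`, `"CHH"`,
#'   `"undetermined"`, or `NA` when the base at `pos` on `strand` is not a
#'   cytosine.
#' @examples
#' assign_context("ACGT", 1)        # "CG"
#' assign_context("ACAGT", 1)       # "CHG"
#' assign_context("ACGT", 2, "-")   # "CG" on the minus strand
#' @export
assign_context <- function(sequence, pos, strand = "+") {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (any(pos < 0 | pos >= L)) {
    stop_input("position out of bounds: sequence has %d bases", L)
  }
  strand <- rep_len(strand, length(pos))
  base <- chars[pos + 1]
  out <- rep(NA_character_, length(pos))

  at <- function(idx) ifelse(idx >= 1 & idx <= L, chars[pmax(pmin(idx, L), 1)], NA)

  plus <- strand == "+" & base == "C"
  if (any(plus)) {
    b1 <- at(pos + 2)[plus]
    b2 <- at(pos + 3)[plus]
    out[plus] <- ifelse(!is.na(b1) & b1 == "G", "CG",
                 ifelse(is.na(b1), "undetermined",
                 ifelse(!is.na(b2) & b2 == "G", "CHG",
                 ifelse(is.na(b2), "undetermined", "CHH"))))
  }
  minus <- strand == "-" & base == "G"
  if (any(minus)) {
    b1 <- at(pos)[minus]       # next base in minus-strand reading order
    b2 <- at(pos - 1)[minus]
    out[minus] <- ifelse(!is.na(b1) & b1 == "C", "CG",
                  ifelse(is.na(b1), "undetermined",
                  ifelse(!is.na(b2) & b2 == "C", "CHG",
                  ifelse(is.na(b2), "undetermined", "CHH"))))
  }
  out
}

# All determinable cytosines of one sequence, both strands.
# Returns tibble(pos, strand, context) with 0-based positions.
contexts_for_seq <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  pos_plus <- which(chars == "C") - 1L
  pos_minus <- which(chars == "G") - 1L
  res <- bind_rows(
    tibble(pos = pos_plus, strand = "+",
           context = if (length(pos_plus)) assign_context(sequence, pos_plus, "+")
                     else character(0)),
    tibble(pos = pos_minus, strand = "-",
           context = if (length(pos_minus)) assign_context(sequence, pos_minus, "-")
                     else character(0))
  )
  res <- res[!is.na(res$context) & res$context != "undetermined", , drop = FALSE]
  arrange(res, .data$pos, .data$strand)
}

#' Flag reads that failed bisulfite conversion
#'
#' A read is flagged as unconverted when it carries three or more consecutive
#' methylated CHH calls; "consecutive" means adjacent CHH calls in read
#' order, ignoring any CG or CHG calls interleaved between them. This is the
#' standard heuristic for incomplete conversion: a genuine failure leaves
#' every cytosine (in particular the normally near-unmethylated CHH sites)
#' reading as methylated.
#'
#' @param calls Character vector of per-read methylation call strings in
#'   Bismark-style code: `Z`/`z` methylated/unmethylated CG, `X`/`x` CHG,
#'   `H`/`h` CHH.
#' @return Logical vector: `TRUE` for reads to discard.
#' @examples
#' is_unconverted(c("HHH", "HHzH", "HhHH", "ZZZZZ"))
#' @export
is_unconverted <- function(calls) {
  chh_only <- gsub("[^Hh]", "", calls)
  grepl("HHH", chh_only, fixed = TRUE)
}

#' Partition reads into converted and unconverted sets
#'
#' Applies [is_unconverted()] and splits the input, preserving order within
#' each part.
#'
#' @param reads A data frame with a `calls` column (see [is_unconverted()]),
#'   or a bare character vector of call strings.
#' @return A list with elements `kept` and `removed`, each of the same type
#'   as the input.
#' @export
filter_unconverted_reads <- function(reads) {
  calls <- if (is.data.frame(reads)) {
    if (!"calls" %in% names(reads)) stop_input("`reads` needs a `calls` column")
    reads$calls
  } else {
    reads
  }
  bad <- is_unconverted(calls)
  if (is.data.frame(reads)) {
    list(kept = reads[!bad, , drop = FALSE], removed = reads[bad, , drop = FALSE])
  } else {
    list(kept = reads[!bad], removed = reads[bad])
  }
}

#' Methylation level
#'
#' The fraction of methylated calls, `#mC / (#mC + #unmC)`. Undefined (and
#' returned as `NA`, never 0) when a cytosine has no coverage.
#'
#' @param n_meth,n_unmeth Non-negative counts, vectorized.
#' @return Numeric fraction(s) in `[0, 1]`, `NA` where both counts are 0.
#' @examples
#' methylation_level(3, 1)  # 0.75
#' methylation_level(0, 0)  # NA
#' @export
methylation_level <- function(n_meth, n_unmeth) {
  if (any(n_meth < 0, na.rm = TRUE) || any(n_unmeth < 0, na.rm = TRUE)) {
    stop_input("methylation counts must be non-negative")
  }
  tot <- n_meth + n_unmeth
  ifelse(tot > 0, n_meth / tot, NA_real_)
}

check_context <- function(context) {
  if (!all(context %in% c("CG", "CHG", "CHH"))) {
    stop_input("unknown context '%s' (expected CG, CHG or CHH)",
               paste(setdiff(context, c("CG", "CHG", "CHH")), collapse = ","))
  }
  context
}

# Window grid for a genome model: fixed-width tiling from coordinate 0,
# the last partial window reported with its true span.
window_grid <- function(genome, window) {
  gm <- as_genome_model(genome)
  purrr::map_dfr(seq_len(nrow(gm$chromosomes)), function(i) {
    L <- gm$chromosomes$length[i]
    starts <- seq(0, L - 1, by = window)
    tibble(chrom = gm$chromosomes$chrom[i], start = starts,
           end = pmin(starts + window, L))
  })
}

#' Pooled methylation in tiling windows
#'
#' Tiles each chromosome with fixed-width windows from coordinate 0 (the
#' final partial window keeps its true span) and computes the depth-pooled
#' methylation level per window and context:
#' `sum(n_meth) / sum(n_meth + n_unmeth)` over the covered cytosines in the
#' window. Windows with no covered cytosines are reported with `level = NA`,
#' never 0. `pool = "site"` instead averages the per-cytosine levels
#' (unweighted), for comparison.
#'
#' @param report Cytosine report tibble: `chrom`, `pos` (0-based), `strand`,
#'   `context`, `n_meth`, `n_unmeth`.
#' @param genome A `genome_model` or `sim_genome` supplying chromosome
#'   lengths.
#' @param window Window width, bp (default 10,000).
#' @param context Optional single context (`"CG"`, `"CHG"`, `"CHH"`) to
#'   restrict to; by default all three are reported as separate rows.
#' @param pool `"depth"` (default, depth-weighted pooling) or `"site"`
#'   (mean of per-site levels).
#' @return Tibble: `chrom`, `start`, `end`, `context`, `level`,
#'   `n_cytosines`, `total_depth`.
#' @export
window_methylation <- function(report, genome, window = 10000, context = NULL,
                               pool = c("depth", "site")) {
  pool <- match.arg(pool)
  if (!is.numeric(window) || length(window) != 1 || window <= 0) {
    stop_input("`window` must be a positive width in bp")
  }
  contexts <- if (is.null(context)) c("CG", "CHG", "CHH") else check_context(context)
  grid <- window_grid(genome, window)
  grid <- tidyr::crossing(grid, context = contexts)
  rep_sub <- report[report$context %in% contexts, , drop = FALSE]
  agg <- rep_sub |>
    mutate(start = floor(.data$pos / window) * window) |>
    group_by(.data$chrom, .data$start, .data$context) |>
    summarise(
      level = if (pool == "depth") {
        methylation_level(sum(.data$n_meth), sum(.data$n_unmeth))
      } else {
        mean(methylation_level(.data$n_meth, .data$n_unmeth), na.rm = TRUE)
      },
      n_cytosines = dplyr::n(),
      total_depth = sum(.data$n_meth + .data$n_unmeth),
      .groups = "drop"
    )
  grid |>
    left_join(agg, by = c("chrom", "start", "context")) |>
    mutate(
      n_cytosines = dplyr::coalesce(.data$n_cytosines, 0L),
      total_depth = dplyr::coalesce(.data$total_depth, 0),
      level = ifelse(is.nan(.data$level), NA_real_, .data$level)
    ) |>
    arrange(.data$chrom, .data$start, .data$context)
}

#' Estimate the bisulfite conversion rate
#'
#' One minus the depth-pooled methylation level over every cytosine of the
#' unmethylated control contig: any methylated call there is a conversion
#' failure.
#'
#' @param report Cytosine report tibble (see [window_methylation()]).
#' @param control_contig Name of the unmethylated control contig.
#' @return A fraction in `[0, 1]`.
#' @export
conversion_rate <- function(report, control_contig) {
  ctrl <- report[report$chrom == control_contig, , drop = FALSE]
  if (nrow(ctrl) == 0) {
    stop_input("control contig '%s' absent from the report", control_contig)
  }
  1 - methylation_level(sum(ctrl$n_meth), sum(ctrl$n_unmeth))
}
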