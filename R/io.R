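# All on-disk coordinates follow the BED convention: 0-based, half-open.
# Cytosine reports are the one format where 1-based input exists in the wild
# (Bismark-style); the reader converts at the boundary via `one_based`.

bed_label_cols <- c("class", "lenclass")

#' Read a BED3-BED6 file
#'
#' Reads a plain-text BED file into a sorted feature tibble. Key=value
#' segments in the name field (e.g. `TE001;class=heterochromatic;lenclass=long`)
#' are decoded into their own columns; [write_bed()] re-encodes them, so the
#' round trip is lossless. Malformed intervals are reported with their line
#' number.
#'
#' @param path File path.
#' @return Feature tibble with `chrom`, `start`, `end` and any of `name`,
#'   `score`, `strand`, plus decoded label columns.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_input("BED file not found: %s", path)
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) stop_input("BED file is empty: %s", path)
  if (ncol(raw) < 3) stop_parse("%s: expected at least 3 tab-separated columns", path)
  out <- tibble(
    chrom = raw[[1]],
    start = suppressWarnings(as.double(raw[[2]])),
    end = suppressWarnings(as.double(raw[[3]]))
  )
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad) > 0) {
    stop_parse("%s line %d: non-numeric coordinates", path, bad[1])
  }
  bad <- which(out$end <= out$start)
  if (length(bad) > 0) {
    stop_parse("%s line %d: end <= start", path, bad[1])
  }
  if (ncol(raw) >= 4) {
    segs <- strsplit(raw[[4]], ";", fixed = TRUE)
    is_kv <- lapply(segs, grepl, pattern = "=", fixed = TRUE)
    out$name <- purrr::map2_chr(segs, is_kv, function(s, kv) {
      plain <- s[!kv]
      if (length(plain) == 0) "." else paste(plain, collapse = ";")
    })
    kvs <- purrr::map2(segs, is_kv, ~ .x[.y])
    keys <- unique(unlist(lapply(kvs, function(s) sub("=.*", "", s))))
    for (key in keys) {
      out[[key]] <- purrr::map_chr(kvs, function(s) {
        hit <- s[startsWith(s, paste0(key, "="))]
        if (length(hit) == 0) NA_character_ else sub("^[^=]*=", "", hit[1])
      })
    }
  }
  if (ncol(raw) >= 5) out$score <- suppressWarnings(as.double(raw[[5]]))
  if (ncol(raw) >= 6) out$strand <- raw[[6]]
  sort_intervals(out)
}

#' Write features as BED
#'
#' Writes a sorted BED3-BED6 file. Label columns (`class`, `lenclass`, and
#' any column previously decoded by [read_bed()]) are encoded into the name
#' field as `name;key=value;...`.
#'
#' @param features Feature tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(features, path) {
  check_intervals(features, "features")
  x <- sort_intervals(as_tibble(features))
  label_cols <- intersect(bed_label_cols, names(x))
  extra <- setdiff(names(x), c("chrom", "start", "end", "name", "score", "strand",
                               bed_label_cols))
  label_cols <- c(label_cols, extra[vapply(x[extra], is.character, logical(1))])
  cols <- list(x$chrom, format_coord(x$start), format_coord(x$end))
  has_name <- "name" %in% names(x) || length(label_cols) > 0
  if (has_name) {
    name <- if ("name" %in% names(x)) x$name else rep(".", nrow(x))
    for (key in label_cols) {
      name <- paste0(name, ";", key, "=", x[[key]])
    }
    cols <- c(cols, list(name))
    if ("score" %in% names(x)) {
      cols <- c(cols, list(x$score))
      if ("strand" %in% names(x)) cols <- c(cols, list(x$strand))
    } else if ("strand" %in% names(x)) {
      cols <- c(cols, list(rep(0, nrow(x)), x$strand))
    }
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a bedGraph coverage track
#'
#' Four tab-separated columns (chrom, start, end, value), 0-based half-open.
#' Runs must be non-overlapping; overlapping runs are a parse error.
#'
#' @param path File path.
#' @return Coverage track tibble.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop_input("bedGraph file not found: %s", path)
  raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                         col_types = "cddd", progress = FALSE)
  bad <- which(is.na(raw$start) | is.na(raw$end) | is.na(raw$value))
  if (length(bad) > 0) stop_parse("%s line %d: malformed record", path, bad[1])
  bad <- which(raw$end <= raw$start)
  if (length(bad) > 0) stop_parse("%s line %d: end <= start", path, bad[1])
  t <- sort_intervals(raw)
  for (idx in split(seq_len(nrow(t)), t$chrom)) {
    if (length(idx) > 1) {
      ov <- which(t$start[idx][-1] < t$end[idx][-length(idx)])
      if (length(ov) > 0) {
        stop_parse("%s: overlapping runs on %s near position %s", path,
                   t$chrom[idx][1], format_coord(t$start[idx][ov[1] + 1]))
      }
    }
  }
  t
}

#' Write a coverage track as bedGraph
#'
#' @param track Coverage track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  t <- check_track(track)
  lines <- paste(t$chrom, format_coord(t$start), format_coord(t$end),
                 format(t$value, scientific = FALSE, trim = TRUE, digits = 10),
                 sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a per-cytosine methylation report
#'
#' Tab-separated with a header: `chrom`, `pos`, `strand`, `context`,
#' `n_meth`, `n_unmeth`. Positions are 0-based by default; Bismark-style
#' 1-based reports are accepted with `one_based = TRUE` (converted at this
#' boundary only, everything downstream is 0-based).
#'
#' @param path File path.
#' @param one_based Input positions are 1-based.
#' @return Cytosine report tibble.
#' @export
read_cytosine_report <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop_input("cytosine report not found: %s", path)
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "d", strand = "c", context = "c",
    n_meth = "d", n_unmeth = "d"
  ), progress = FALSE)
  if (one_based) x$pos <- x$pos - 1
  if (any(x$pos < 0)) stop_parse("%s: negative positions after conversion", path)
  check_context(unique(x$context))
  if (any(x$n_meth < 0 | x$n_unmeth < 0)) stop_parse("%s: negative counts", path)
  x
}

#' Write a per-cytosine methylation report
#'
#' @param report Cytosine report tibble (0-based positions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(report, path) {
  readr::write_tsv(report[, c("chrom", "pos", "strand", "context",
                              "n_meth", "n_unmeth")], path, progress = FALSE)
  invisible(path)
}

#' Write genome sequences as FASTA
#'
#' @param genome A `sim_genome` or named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "sim_genome")) genome$seq else genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop_input("FASTA file not found: %s", path)
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}
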