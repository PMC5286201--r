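#' Read and write simulation truth files (extended BED)
#'
#' Truth files are tab-separated extended BED: `chrom start end type copies
#' chrom2 pos2 ins_seq` with `.` for missing fields, 0-based half-open
#' coordinates on disk. On read they are converted to the internal 1-based
#' inclusive convention ([truth_records()]); `write_truth_bed()` is the
#' exact inverse, so read/write round-trips are the identity.
#'
#' @param path File path.
#' @return `read_truth_bed()`: a truth tibble. `write_truth_bed()`:
#'   `path`, invisibly.
#' @export
read_truth_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) return(empty_truth_tbl())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4)) {
    abort(sprintf("read_truth_bed(): line %d has %d column(s); need >= 4",
                  which(nf < 4)[1], nf[which(nf < 4)[1]]),
          class = "svkit_format_error")
  }
  get <- function(k) vapply(parts, function(p) {
    v <- if (length(p) >= k) p[k] else "."
    if (v == ".") NA_character_ else v
  }, character(1))
  tbl <- tibble(
    chrom = get(1),
    start = as.integer(get(2)) + 1L,          # 0-based -> 1-based
    end = as.integer(get(3)),
    type = get(4),
    copies = suppressWarnings(as.integer(get(5))),
    chrom2 = get(6),
    pos2 = suppressWarnings(as.integer(get(7)) + 1L),
    ins_seq = get(8)
  )
  if ("id" %in% names(tbl)) tbl$id <- NULL
  truth_records(tbl)
}

#' @rdname read_truth_bed
#' @param records Truth tibble ([truth_records()]).
#' @export
write_truth_bed <- function(records, path) {
  records <- truth_records(records)
  fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
  lines <- paste(
    records$chrom,
    records$start - 1L,                        # 1-based -> 0-based
    records$end,
    records$type,
    fmt(records$copies),
    fmt(records$chrom2),
    fmt(records$pos2 - 1L),
    fmt(records$ins_seq),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read annotation intervals from BED
#'
#' Plain 3+ column BED; the optional 4th column becomes the interval label.
#' Coordinates stay in the BED convention (0-based half-open) inside the
#' returned [interval_set()]. Malformed lines are dropped with a message,
#' not an error.
#'
#' @param path BED file.
#' @return An [interval_set()].
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) return(interval_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 3
  if (any(!ok)) {
    inform(paste0("read_intervals(): dropped ", sum(!ok),
                  " line(s) with < 3 columns"))
    parts <- parts[ok]
  }
  interval_set(tibble(
    chrom = vapply(parts, `[`, character(1), 1),
    start = as.integer(vapply(parts, `[`, character(1), 2)),
    end = as.integer(vapply(parts, `[`, character(1), 3)),
    label = vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_,
                   character(1))
  ))
}

#' Read a windowed coverage matrix
#'
#' Tab-separated with header `chrom start end strain1 ... strainN`;
#' windows are fixed-width, 0-based half-open, sorted and non-overlapping.
#'
#' @param path TSV file.
#' @return Tibble with `chrom`, `start`, `end` and one count column per
#'   strain.
#' @export
read_coverage_tsv <- function(path) {
  cov <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(cov))) {
    abort("read_coverage_tsv(): need columns chrom, start, end",
          class = "svkit_format_error")
  }
  cov
}
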