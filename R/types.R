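#' Structural variant types
#'
#' The closed set of structural variant (SV) classes the toolkit handles:
#' deletion (`DEL`), duplication (`DUP`), insertion (`INS`), inversion
#' (`INV`) and translocation (`TRA`). Any other type string coming from an
#' input file raises an error of class `svkit_type_error`.
#'
#' @return Character vector of the five recognised SV type codes.
#' @export
#' @examples
#' sv_types()
sv_types <- function() c("DEL", "DUP", "INS", "INV", "TRA")

cnv_types <- function() c("DEL", "DUP")

assert_sv_type <- function(type, context = "record") {
  bad <- setdiff(unique(as.character(type)), sv_types())
  if (length(bad) > 0) {
    abort(
      paste0(
        "Unknown SV type(s) in ", context, ": ",
        paste(bad, collapse = ", "),
        ". Allowed: ", paste(sv_types(), collapse = ", ")
      ),
      class = "svkit_type_error"
    )
  }
  invisible(type)
}

sv_call_cols <- function() {
  c("id", "type", "chrom", "start", "end", "chrom2", "pos2",
    "length", "pe_support", "caller")
}

empty_sv_tbl <- function() {
  tibble(
    id = character(), type = character(), chrom = character(),
    start = integer(), end = integer(), chrom2 = character(),
    pos2 = integer(), length = integer(), pe_support = integer(),
    caller = character()
  )
}

#' Construct a tibble of SV calls
#'
#' One row per structural variant call. Coordinates are 1-based inclusive
#' (VCF-like). Translocations (`TRA`) carry their partner locus in
#' `chrom2`/`pos2`; all other types must leave those columns `NA`.
#' Missing paired-end support is `NA` (unknown), which downstream filters
#' treat differently from zero.
#'
#' @param df Data frame with at least `type`, `chrom`, `start`, `end`.
#'   Optional columns: `id`, `chrom2`, `pos2`, `length`, `pe_support`,
#'   `caller`. Extra columns are preserved.
#' @param caller Default caller label applied where `caller` is absent.
#'
#' @return A validated tibble with the canonical SV-call columns first.
#' @export
#' @examples
#' sv_calls(data.frame(type = "DEL", chrom = "I", start = 1001, end = 2000))
sv_calls <- function(df, caller = "unknown") {
  df <- as_tibble(df)
  if (nrow(df) == 0 && ncol(df) == 0) return(empty_sv_tbl())
  need <- c("type", "chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("sv_calls(): missing column(s): ", paste(miss, collapse = ", ")),
          class = "svkit_format_error")
  }
  if (!"id" %in% names(df)) df$id <- sprintf("sv%05d", seq_len(nrow(df)))
  if (!"chrom2" %in% names(df)) df$chrom2 <- NA_character_
  if (!"pos2" %in% names(df)) df$pos2 <- NA_integer_
  if (!"length" %in% names(df)) df$length <- NA_integer_
  if (!"pe_support" %in% names(df)) df$pe_support <- NA_integer_
  if (!"caller" %in% names(df)) df$caller <- caller
  df <- mutate(df,
    id = as.character(.data$id), type = as.character(.data$type),
    chrom = as.character(.data$chrom), start = as.integer(.data$start),
    end = as.integer(.data$end), chrom2 = as.character(.data$chrom2),
    pos2 = as.integer(.data$pos2), length = as.integer(.data$length),
    pe_support = as.integer(.data$pe_support), caller = as.character(.data$caller)
  )
  validate_sv_calls(df)
  select(df, all_of(sv_call_cols()), dplyr::everything())
}

validate_sv_calls <- function(df) {
  assert_sv_type(df$type, "SV calls")
  non_tra <- df$type != "TRA"
  if (any(non_tra & (is.na(df$start) | is.na(df$end) | df$start > df$end))) {
    abort("sv_calls(): non-TRA records require start <= end", class = "svkit_format_error")
  }
  if (any(non_tra & !is.na(df$chrom2))) {
    abort("sv_calls(): chrom2 must be absent for non-TRA records", class = "svkit_format_error")
  }
  if (any(!non_tra & (is.na(df$chrom2) | is.na(df$pos2)))) {
    abort("sv_calls(): TRA records require chrom2 and pos2", class = "svkit_format_error")
  }
  if (any(!is.na(df$pe_support) & df$pe_support < 0)) {
    abort("sv_calls(): pe_support must be >= 0 when present", class = "svkit_format_error")
  }
  invisible(df)
}

#' Construct a tibble of simulation truth records
#'
#' Truth records describe simulated SVs on *reference* coordinates
#' (1-based inclusive). Duplications carry `copies` (total tandem copy
#' count, >= 2), insertions carry the inserted sequence `ins_seq`, and
#' translocations carry the partner junction in `chrom2`/`pos2`.
#'
#' @param df Data frame with `type`, `chrom`, `start`, `end` and the
#'   optional columns above.
#' @return Validated tibble, one row per simulated event.
#' @export
truth_records <- function(df) {
  df <- as_tibble(df)
  if (nrow(df) == 0 && ncol(df) == 0) return(empty_truth_tbl())
  need <- c("type", "chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("truth_records(): missing column(s): ", paste(miss, collapse = ", ")),
          class = "svkit_format_error")
  }
  if (!"id" %in% names(df)) df$id <- sprintf("%s%05d", df$type, seq_len(nrow(df)))
  if (!"chrom2" %in% names(df)) df$chrom2 <- NA_character_
  if (!"pos2" %in% names(df)) df$pos2 <- NA_integer_
  if (!"copies" %in% names(df)) df$copies <- NA_integer_
  if (!"ins_seq" %in% names(df)) df$ins_seq <- NA_character_
  df <- mutate(df,
    id = as.character(.data$id), type = as.character(.data$type),
    chrom = as.character(.data$chrom), start = as.integer(.data$start),
    end = as.integer(.data$end), chrom2 = as.character(.data$chrom2),
    pos2 = as.integer(.data$pos2), copies = as.integer(.data$copies),
    ins_seq = as.character(.data$ins_seq)
  )
  assert_sv_type(df$type, "truth records")
  if (any(df$type == "DUP" & (is.na(df$copies) | df$copies < 2))) {
    abort("truth_records(): DUP requires copies >= 2", class = "svkit_format_error")
  }
  if (any(df$type == "TRA" & (is.na(df$chrom2) | is.na(df$pos2)))) {
    abort("truth_records(): TRA requires chrom2 and pos2", class = "svkit_format_error")
  }
  select(df, all_of(c("id", "type", "chrom", "start", "end", "chrom2", "pos2",
                      "copies", "ins_seq")))
}

empty_truth_tbl <- function() {
  tibble(
    id = character(), type = character(), chrom = character(),
    start = integer(), end = integer(), chrom2 = character(),
    pos2 = integer(), copies = integer(), ins_seq = character()
  )
}

#' Construct an interval set
#'
#' Annotation intervals (for example retrotransposon LTRs or low
#' mapping-quality regions) kept in BED convention: 0-based half-open
#' `[start, end)`. Intervals are sorted; overlapping or touching intervals
#' are retained as given.
#'
#' @param df Data frame with `chrom`, `start`, `end` and optional `label`.
#' @return Sorted tibble of class `svkit_intervals`.
#' @export
interval_set <- function(df = NULL) {
  if (is.null(df) || nrow(as_tibble(df)) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  label = character())
  } else {
    df <- as_tibble(df)
    if (!"label" %in% names(df)) df$label <- NA_character_
    out <- df |>
      mutate(chrom = as.character(.data$chrom), start = as.integer(.data$start),
             end = as.integer(.data$end), label = as.character(.data$label)) |>
      select(all_of(c("chrom", "start", "end", "label"))) |>
      arrange(.data$chrom, .data$start, .data$end)
    if (any(out$start < 0 | out$end < out$start)) {
      abort("interval_set(): require 0 <= start <= end", class = "svkit_format_error")
    }
  }
  class(out) <- c("svkit_intervals", class(out))
  out
}

#' Test genomic points for interval membership
#'
#' Membership follows the half-open BED rule: a 1-based position `p` lies in
#' a 0-based interval `[s, e)` iff `s < p <= e`.
#'
#' @param chrom,pos Vectors (recycled to common length) of chromosome names
#'   and 1-based positions.
#' @param intervals An [interval_set()].
#' @return Logical vector, `TRUE` where the point falls in any interval.
#' @export
points_in_intervals <- function(chrom, pos, intervals) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  if (is.null(intervals) || nrow(intervals) == 0) return(rep(FALSE, n))
  vapply(seq_len(n), function(i) {
    any(intervals$chrom == chrom[i] &
          intervals$start < pos[i] & pos[i] <= intervals$end)
  }, logical(1))
}

# seed handling: all stochastic svkit functions accept `seed`; when non-NULL
# the RNG state is set locally and restored on exit.
local_seed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed), .local_envir = env)
  invisible(seed)
}
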