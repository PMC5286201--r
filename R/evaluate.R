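#' Match predicate between a call and a truth record
#'
#' A call matches a truth record iff (i) they are the same SV type, (ii)
#' on the same chromosome(s), and (iii) both start and end coordinates
#' agree within `tolerance_bp` (default 1 kb). For translocations the two
#' junction loci are compared as an unordered pair: both pairings are
#' tried, and both loci must agree within tolerance.
#'
#' @param calls,truth Tibbles of calls and truth records; rows are paired
#'   elementwise (recycled if one has a single row).
#' @param tolerance_bp Breakpoint tolerance in bp, >= 0.
#' @return Logical vector.
#' @export
#' @examples
#' truth <- truth_records(data.frame(type = "DEL", chrom = "II",
#'                                   start = 1488036, end = 1489773))
#' call <- sv_calls(data.frame(type = "DEL", chrom = "II",
#'                             start = 1488228, end = 1489646))
#' sv_match(call, truth)   # TRUE: both breakpoints within 1 kb
sv_match <- function(calls, truth, tolerance_bp = 1000) {
  if (tolerance_bp < 0) abort("sv_match(): tolerance_bp must be >= 0",
                              class = "svkit_parameter_error")
  n <- max(nrow(calls), nrow(truth))
  ci <- rep_len(seq_len(nrow(calls)), n)
  ti <- rep_len(seq_len(nrow(truth)), n)
  c_ <- calls[ci, ]; t_ <- truth[ti, ]
  same_type <- c_$type == t_$type
  non_tra <- same_type & c_$type != "TRA" &
    c_$chrom == t_$chrom &
    abs(c_$start - t_$start) <= tolerance_bp &
    abs(c_$end - t_$end) <= tolerance_bp
  tra_fwd <- c_$chrom == t_$chrom & c_$chrom2 == t_$chrom2 &
    abs(c_$start - t_$start) <= tolerance_bp &
    abs(c_$pos2 - t_$pos2) <= tolerance_bp
  tra_rev <- c_$chrom == t_$chrom2 & c_$chrom2 == t_$chrom &
    abs(c_$start - t_$pos2) <= tolerance_bp &
    abs(c_$pos2 - t_$start) <= tolerance_bp
  tra <- same_type & c_$type == "TRA" &
    (dplyr::coalesce(tra_fwd, FALSE) | dplyr::coalesce(tra_rev, FALSE))
  dplyr::coalesce(non_tra, FALSE) | tra
}

# calls x truth logical match matrix
match_matrix <- function(calls, truth, tolerance_bp = 1000) {
  m <- matrix(FALSE, nrow(calls), nrow(truth))
  if (nrow(calls) == 0 || nrow(truth) == 0) return(m)
  for (j in seq_len(nrow(truth))) {
    m[, j] <- sv_match(calls, truth[j, ], tolerance_bp)
  }
  m
}

#' Evaluate a callset against a truth set
#'
#' Scores sensitivity and false discovery rate (FDR) under the breakpoint
#' match predicate ([sv_match()]). Counting is many-to-many: a truth
#' record is a true positive if matched by at least one call, and a call
#' is a false positive if it matches no truth record; no one-to-one
#' assignment is made, so both rates are monotone in the tolerance.
#' Per-type breakdowns accompany the pooled numbers (matches never cross
#' types).
#'
#' @param calls Tibble of SV calls.
#' @param truth Truth tibble.
#' @param tolerance_bp Breakpoint tolerance in bp (default 1000; a 2 kb
#'   tolerance is conventional for window-based CNV callers).
#' @return Object of class `sv_evaluation`: list with `summary` (pooled
#'   one-row tibble) and `per_type`. With empty truth the sensitivity is
#'   `NaN` (with a warning); with empty calls the FDR is `NaN` likewise.
#' @export
evaluate_calls <- function(calls, truth, tolerance_bp = 1000) {
  if (tolerance_bp < 0) abort("evaluate_calls(): tolerance_bp must be >= 0",
                              class = "svkit_parameter_error")
  calls <- sv_calls(calls)
  truth <- truth_records(truth)
  if (nrow(truth) == 0) warn("evaluate_calls(): empty truth; sensitivity is NaN")
  if (nrow(calls) == 0) warn("evaluate_calls(): empty callset; FDR is NaN")
  m <- match_matrix(calls, truth, tolerance_bp)
  score <- function(ci, ti) {
    nt <- length(ti); nc <- length(ci)
    tp <- if (nt) sum(apply(m[ci, ti, drop = FALSE], 2, any)) else 0L
    fp <- if (nc) sum(!apply(m[ci, ti, drop = FALSE], 1, any)) else 0L
    tibble(
      n_truth = nt, n_calls = nc, tp_truth = tp, fp_calls = fp,
      fn = nt - tp,
      sensitivity = if (nt) tp / nt else NaN,
      fdr = if (nc) fp / nc else NaN
    )
  }
  pooled <- score(seq_len(nrow(calls)), seq_len(nrow(truth)))
  types <- sort(unique(c(calls$type, truth$type)))
  per_type <- purrr::map_dfr(types, function(ty) {
    mutate(score(which(calls$type == ty), which(truth$type == ty)),
           type = ty, .before = 1)
  })
  structure(
    list(summary = pooled, per_type = per_type, tolerance_bp = tolerance_bp),
    class = "sv_evaluation"
  )
}

#' @export
print.sv_evaluation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "SV evaluation (tolerance %d bp): %d truth, %d calls\n  sensitivity %.3f (TP %d/%d), FDR %.3f (FP %d/%d)\n",
    x$tolerance_bp, s$n_truth, s$n_calls, s$sensitivity, s$tp_truth,
    s$n_truth, s$fdr, s$fp_calls, s$n_calls
  ))
  invisible(x)
}

#' @rdname evaluate_calls
#' @param x An `sv_evaluation`.
#' @param ... Unused.
#' @export
tidy.sv_evaluation <- function(x, ...) {
  bind_rows(mutate(x$summary, type = "all", .before = 1), x$per_type)
}

#' @rdname evaluate_calls
#' @export
glance.sv_evaluation <- function(x, ...) {
  mutate(x$summary, tolerance_bp = x$tolerance_bp)
}

#' @rdname evaluate_calls
#' @param object An `sv_evaluation`.
#' @export
autoplot.sv_evaluation <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("sensitivity", "fdr"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "SV type", y = NULL, fill = NULL,
                  title = sprintf("Callset evaluation (tolerance %d bp)",
                                  object$tolerance_bp)) +
    ggplot2::theme_minimal()
}
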