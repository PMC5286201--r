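# single-linkage clustering of calls under the pairwise match predicate.
# Candidate pairs are generated within (type, chrom-set) groups; transitive
# closure via graph components.
cluster_calls <- function(calls, tolerance_bp = 1000) {
  n <- nrow(calls)
  if (n == 0) return(integer(0))
  key <- ifelse(calls$type == "TRA",
                paste0("TRA|", pmin(calls$chrom, calls$chrom2), "|",
                       pmax(calls$chrom, calls$chrom2)),
                paste0(calls$type, "|", calls$chrom))
  edges <- list()
  for (g in unique(key)) {
    idx <- which(key == g)
    if (length(idx) < 2) next
    pr <- t(combn(idx, 2))
    ok <- sv_match(calls[pr[, 1], ], calls[pr[, 2], ], tolerance_bp) |
      sv_match_as_truth(calls[pr[, 1], ], calls[pr[, 2], ], tolerance_bp)
    edges[[length(edges) + 1]] <- pr[ok, , drop = FALSE]
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(em) && nrow(em) > 0) g <- igraph::add_edges(g, t(em))
  comp <- igraph::components(g)$membership
  # renumber components by first member index for order-independence
  match(comp, unique(comp[order(seq_len(n))]))
}

# symmetric use of the predicate between two callsets (calls vs calls)
sv_match_as_truth <- function(a, b, tolerance_bp) {
  sv_match(b, a, tolerance_bp)
}

# consensus coordinate: member median, floored to an integer position
# (for a pair of calls this is the midpoint)
consensus_coord <- function(x) as.integer(floor(median(x)))

max_or_na <- function(x) {
  if (all(is.na(x))) NA_integer_ else as.integer(max(x, na.rm = TRUE))
}

cluster_representative <- function(members, caller_label = NULL) {
  rep1 <- members[1, ]
  rep1$start <- consensus_coord(members$start)
  rep1$end <- consensus_coord(members$end)
  if (rep1$type == "TRA") {
    rep1$pos2 <- consensus_coord(members$pos2)
  } else if (rep1$type == "INS") {
    rep1$length <- max_or_na(members$length)
  } else {
    rep1$length <- rep1$end - rep1$start + 1L
  }
  rep1$pe_support <- max_or_na(members$pe_support)
  if (!is.null(caller_label)) rep1$caller <- caller_label
  rep1
}

#' Merge duplicate calls within one callset
#'
#' Single-linkage clusters of calls matching under the 1-kb breakpoint
#' predicate (same type, same chromosome, start and end within
#' `tolerance_bp`) collapse to a single representative whose coordinates
#' are the per-coordinate median of the members (lower median for even
#' cluster sizes) and whose paired-end support is the member maximum.
#' Idempotent: merging a merged callset changes nothing.
#'
#' @param calls Calls from a single caller (mixed caller labels are an
#'   error; use [cluster_across_callsets()] for that).
#' @param tolerance_bp Breakpoint tolerance in bp.
#' @return Tibble of merged calls (never more rows than the input).
#' @export
merge_within_callset <- function(calls, tolerance_bp = 1000) {
  calls <- sv_calls(calls)
  if (nrow(calls) == 0) return(calls)
  if (dplyr::n_distinct(calls$caller) > 1) {
    abort("merge_within_callset(): calls carry more than one caller label",
          class = "svkit_precondition_error")
  }
  cl <- cluster_calls(calls, tolerance_bp)
  out <- purrr::map_dfr(split(seq_len(nrow(calls)), cl),
                        function(i) cluster_representative(calls[i, ]))
  sv_calls(arrange(out, .data$chrom, .data$start))
}

#' Cluster calls across multiple callers
#'
#' Pools per-caller callsets (each ideally already deduplicated with
#' [merge_within_callset()]) and forms single-linkage clusters under the
#' same match predicate. Single linkage is the transitive closure of the
#' pairwise rule, so chained calls (A~B, B~C, A!~C) join one cluster.
#'
#' @param callsets A list of call tibbles, or one tibble with a `caller`
#'   column distinguishing sources.
#' @param tolerance_bp Breakpoint tolerance in bp.
#' @return Tibble of all calls with a `cluster_id` column; summary per
#'   cluster via [consensus_filter()] or `attr(, "clusters")`.
#' @export
cluster_across_callsets <- function(callsets, tolerance_bp = 1000) {
  calls <- if (is.data.frame(callsets)) sv_calls(callsets) else
    sv_calls(bind_rows(lapply(callsets, sv_calls)))
  if (nrow(calls) == 0) {
    calls$cluster_id <- integer(0)
    return(calls)
  }
  calls$cluster_id <- cluster_calls(calls, tolerance_bp)
  calls
}

#' Keep clusters supported by a minimum number of callers
#'
#' Implements the majority-vote step: clusters reported by fewer than
#' `min_callers` *distinct* callers are discarded (two calls from one
#' caller never count as two voters). Each kept cluster is emitted as one
#' consensus call at the member-median coordinates with caller label
#' `"consensus"` and paired-end support equal to the member maximum.
#'
#' @param clustered Output of [cluster_across_callsets()].
#' @param min_callers Minimum number of distinct callers (default 2).
#' @return Tibble of consensus calls.
#' @export
consensus_filter <- function(clustered, min_callers = 2) {
  if (min_callers < 1) abort("consensus_filter(): min_callers must be >= 1",
                             class = "svkit_parameter_error")
  if (!"cluster_id" %in% names(clustered)) {
    abort("consensus_filter(): input must come from cluster_across_callsets()")
  }
  keep <- clustered |>
    group_by(.data$cluster_id) |>
    filter(dplyr::n_distinct(.data$caller) >= min_callers) |>
    ungroup()
  if (nrow(keep) == 0) return(empty_sv_tbl())
  out <- purrr::map_dfr(
    split(seq_len(nrow(keep)), keep$cluster_id),
    function(i) cluster_representative(keep[i, ], caller_label = "consensus")
  )
  out$cluster_id <- NULL
  sv_calls(arrange(out, .data$chrom, .data$start))
}

#' Filter calls by paired-end read support
#'
#' Discards calls whose paired-end support is below `min_support`
#' (default 11, i.e. support of 10 or less is discarded). Calls with
#' *unknown* support (`NA`) are dropped too, with a warning counting them
#' — unknown is not treated as zero, but it cannot satisfy the evidence
#' requirement either.
#'
#' @param calls Tibble of SV calls.
#' @param min_support Minimum paired-end support to keep.
#' @return Filtered tibble.
#' @export
filter_pe_support <- function(calls, min_support = 11) {
  calls <- sv_calls(calls)
  n_na <- sum(is.na(calls$pe_support))
  if (n_na > 0) {
    warn(paste0("filter_pe_support(): dropped ", n_na,
                " call(s) with unknown paired-end support"))
  }
  filter(calls, !is.na(.data$pe_support) & .data$pe_support >= min_support)
}

#' Filter calls overlapping unreliable regions
#'
#' Drops a call if *either* breakpoint falls in a low mapping-quality
#' region (regions where reads map with MQ=0), or if *both* start and end
#' breakpoints fall inside annotated retrotransposon LTR intervals. For
#' translocations the two junction loci play the role of start/end.
#'
#' @param calls Tibble of SV calls.
#' @param ltr,low_mq [interval_set()]s (BED convention); `NULL` disables
#'   that filter.
#' @return Filtered tibble.
#' @export
filter_by_regions <- function(calls, ltr = NULL, low_mq = NULL) {
  calls <- sv_calls(calls)
  if (nrow(calls) == 0) return(calls)
  bp1_chrom <- calls$chrom
  bp1_pos <- calls$start
  bp2_chrom <- ifelse(calls$type == "TRA", calls$chrom2, calls$chrom)
  bp2_pos <- ifelse(calls$type == "TRA", calls$pos2, calls$end)
  drop <- rep(FALSE, nrow(calls))
  if (!is.null(low_mq)) {
    drop <- drop | points_in_intervals(bp1_chrom, bp1_pos, low_mq) |
      points_in_intervals(bp2_chrom, bp2_pos, low_mq)
  }
  if (!is.null(ltr)) {
    drop <- drop | (points_in_intervals(bp1_chrom, bp1_pos, ltr) &
                      points_in_intervals(bp2_chrom, bp2_pos, ltr))
  }
  calls[!drop, ]
}

#' Full consensus pipeline
#'
#' Runs the complete filtering cascade in order: per-caller 1-kb
#' deduplication, cross-caller clustering, >= `min_callers` consensus
#' vote, paired-end support filter, then region filters. Per-stage
#' in/out counts are attached as the `"audit"` attribute.
#'
#' @param callsets List of per-caller call tibbles.
#' @param tolerance_bp Breakpoint tolerance (bp).
#' @param min_callers Minimum distinct callers per kept cluster.
#' @param min_pe Minimum paired-end support; `NULL` skips the stage.
#' @param ltr,low_mq Optional [interval_set()]s; `NULL` skips.
#' @return Tibble of filtered consensus calls with an `"audit"` attribute.
#' @export
consensus_pipeline <- function(callsets, tolerance_bp = 1000, min_callers = 2,
                               min_pe = 11, ltr = NULL, low_mq = NULL) {
  merged <- lapply(callsets, merge_within_callset, tolerance_bp = tolerance_bp)
  audit <- tibble(stage = "within-caller merge",
                  n_in = sum(vapply(callsets, nrow, integer(1))),
                  n_out = sum(vapply(merged, nrow, integer(1))))
  clustered <- cluster_across_callsets(merged, tolerance_bp)
  cons <- consensus_filter(clustered, min_callers)
  audit <- bind_rows(audit, tibble(stage = "consensus vote",
                                   n_in = nrow(clustered), n_out = nrow(cons)))
  out <- cons
  if (!is.null(min_pe)) {
    kept <- suppressWarnings(filter_pe_support(out, min_pe))
    audit <- bind_rows(audit, tibble(stage = "pe-support filter",
                                     n_in = nrow(out), n_out = nrow(kept)))
    out <- kept
  }
  if (!is.null(ltr) || !is.null(low_mq)) {
    kept <- filter_by_regions(out, ltr = ltr, low_mq = low_mq)
    audit <- bind_rows(audit, tibble(stage = "region filter",
                                     n_in = nrow(out), n_out = nrow(kept)))
    out <- kept
  }
  attr(out, "audit") <- audit
  out
}
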