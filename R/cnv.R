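#' One-sided rank-sum (Wilcoxon/Mann-Whitney) P value
#'
#' For samples below 30 windows each, the P value is exact: the full null
#' distribution of the rank sum over all `choose(n+m, n)` group
#' assignments is enumerated by dynamic programming over (doubled) average
#' ranks, which handles ties exactly. Once either group reaches 30
#' windows the normal approximation with tie correction and continuity
#' correction takes over (the standard large-sample treatment, accurate
#' well within 0.01 by that size).
#'
#' @param x,y Numeric count vectors (length >= 1).
#' @param direction `"greater"` tests a location shift of `x` above `y`;
#'   `"less"` the reverse.
#' @param method `"auto"` (default: exact below 30 per group), `"exact"`
#'   or `"normal"`.
#' @return P value in (0, 1].
#' @export
#' @examples
#' rank_sum_one_sided(c(8, 9, 10), c(1, 2, 3), "greater")  # 1/20
rank_sum_one_sided <- function(x, y, direction = c("greater", "less"),
                               method = c("auto", "exact", "normal")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  if (length(x) < 1 || length(y) < 1) {
    abort("rank_sum_one_sided(): both samples must be non-empty",
          class = "svkit_parameter_error")
  }
  nx <- length(x); ny <- length(y)
  if (method == "auto") {
    method <- if (nx >= 30 || ny >= 30) "normal" else "exact"
  }
  if (method == "normal") {
    return(wilcox.test(x, y, alternative = direction, exact = FALSE,
                       correct = TRUE)$p.value)
  }
  r2 <- as.integer(round(2 * rank(c(x, y))))   # doubled average ranks
  w_obs <- sum(r2[seq_len(nx)])
  cnt <- ranksum_null_counts(r2, nx)           # counts over doubled-rank sums
  total <- sum(cnt)
  sums <- seq_along(cnt) - 1L
  p <- if (direction == "greater") {
    sum(cnt[sums >= w_obs]) / total
  } else {
    sum(cnt[sums <= w_obs]) / total
  }
  min(max(p, 0), 1)
}

# exact null distribution of the x-group rank sum: cnt[s+1] = number of
# nx-subsets of the pooled doubled ranks summing to s
ranksum_null_counts <- function(r2, nx) {
  S <- sum(r2)
  f <- matrix(0, nrow = nx + 1, ncol = S + 1)
  f[1, 1] <- 1
  for (d in r2) {
    kmax <- nx
    for (k in seq(kmax, 1)) {
      src <- f[k, seq_len(S + 1 - d)]
      if (any(src != 0)) {
        f[k + 1, (d + 1):(S + 1)] <- f[k + 1, (d + 1):(S + 1)] + src
      }
    }
  }
  f[nx + 1, ]
}

# windows of a coverage tibble fully inside a 1-based inclusive region
region_windows <- function(cov, region) {
  filter(cov, .data$chrom == region$chrom,
         .data$start + 1L >= region$start, .data$end <= region$end)
}

#' Call a CNV allele for one strain at one region
#'
#' Compares windowed read counts of an alternate strain against two
#' reference strains over a candidate CNV region. The allele is a
#' duplication (`DUP`) only if, *for both references independently*, the
#' one-sided rank-sum P value is below `p_thresh` (direction: alternate
#' greater) and the alternate/reference mean-coverage ratio exceeds
#' `dup_ratio`; a deletion (`DEL`) analogously with direction less and
#' ratio below `del_ratio`; otherwise the reference allele (`REF`). The
#' direction of the one-sided test follows the candidate class, the only
#' reading consistent with a one-sided test plus a two-sided ratio gate.
#' A median-ratio copy number (haploid baseline 1) is reported alongside.
#'
#' @param cov Coverage tibble: `chrom`, `start`, `end` (0-based half-open
#'   fixed-width windows) plus one count column per strain.
#' @param region One-row data frame (or list) with `chrom`, `start`, `end`
#'   in 1-based inclusive coordinates; windows straddling the region
#'   boundary are excluded, and at least 2 windows must remain.
#' @param alt_strain Column name of the strain being genotyped.
#' @param ref_strains Character vector of exactly two reference strain
#'   columns.
#' @param p_thresh Rank-sum P threshold (default 1e-10).
#' @param dup_ratio,del_ratio Coverage-ratio gates (defaults 1.8 and 0.2).
#' @return One-row tibble: `strain`, `region`, `call` (`REF`/`DUP`/`DEL`,
#'   or `NA` with `callable = FALSE` when a reference has zero mean
#'   coverage or fewer than 2 windows lie inside the region), P values and
#'   ratios against each reference, and `copy_number`.
#' @export
call_cnv_allele <- function(cov, region, alt_strain, ref_strains,
                            p_thresh = 1e-10, dup_ratio = 1.8,
                            del_ratio = 0.2) {
  if (length(ref_strains) != 2) {
    abort("call_cnv_allele(): exactly two reference strains required",
          class = "svkit_parameter_error")
  }
  if (alt_strain %in% ref_strains) {
    abort("call_cnv_allele(): alt_strain must differ from the references",
          class = "svkit_parameter_error")
  }
  region <- as_tibble(as.list(region)[c("chrom", "start", "end")])
  region_id <- sprintf("%s:%d-%d", region$chrom, region$start, region$end)
  win <- region_windows(cov, region)
  out <- tibble(
    strain = alt_strain, region = region_id, call = NA_character_,
    p_ref1 = NA_real_, p_ref2 = NA_real_, ratio_ref1 = NA_real_,
    ratio_ref2 = NA_real_, copy_number = NA_real_, callable = FALSE
  )
  if (nrow(win) < 2) return(out)
  alt <- win[[alt_strain]]
  r1 <- win[[ref_strains[1]]]
  r2 <- win[[ref_strains[2]]]
  m1 <- mean(r1); m2 <- mean(r2)
  if (m1 == 0 || m2 == 0) return(out)
  ratio1 <- mean(alt) / m1
  ratio2 <- mean(alt) / m2
  ref_mean <- (r1 + r2) / 2
  cn <- median(ifelse(ref_mean > 0, alt / ref_mean, NA_real_), na.rm = TRUE)

  if (ratio1 > dup_ratio && ratio2 > dup_ratio) {
    p1 <- rank_sum_one_sided(alt, r1, "greater")
    p2 <- rank_sum_one_sided(alt, r2, "greater")
    allele <- if (p1 < p_thresh && p2 < p_thresh) "DUP" else "REF"
  } else if (ratio1 < del_ratio && ratio2 < del_ratio) {
    p1 <- rank_sum_one_sided(alt, r1, "less")
    p2 <- rank_sum_one_sided(alt, r2, "less")
    allele <- if (p1 < p_thresh && p2 < p_thresh) "DEL" else "REF"
  } else {
    p1 <- NA_real_; p2 <- NA_real_
    allele <- "REF"
  }
  mutate(out, call = !!allele, p_ref1 = !!p1, p_ref2 = !!p2,
         ratio_ref1 = !!ratio1, ratio_ref2 = !!ratio2, copy_number = !!cn,
         callable = TRUE)
}

#' Genotype CNV alleles for many strains and regions
#'
#' Applies [call_cnv_allele()] over every region x alternate-strain
#' combination.
#'
#' @inheritParams call_cnv_allele
#' @param regions Data frame of candidate CNV regions (`chrom`, `start`,
#'   `end`, 1-based inclusive; an optional `region_id` column is carried
#'   through).
#' @param alt_strains Strains to genotype; defaults to every count column
#'   except the references.
#' @return Tibble of allele calls, one row per strain x region.
#' @export
genotype_cnv_regions <- function(cov, regions, ref_strains,
                                 alt_strains = NULL, p_thresh = 1e-10,
                                 dup_ratio = 1.8, del_ratio = 0.2) {
  strains <- setdiff(names(cov), c("chrom", "start", "end"))
  alt_strains <- alt_strains %||% setdiff(strains, ref_strains)
  regions <- as_tibble(regions)
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    purrr::map_dfr(alt_strains, function(s) {
      res <- call_cnv_allele(cov, regions[i, ], s, ref_strains,
                             p_thresh, dup_ratio, del_ratio)
      if ("region_id" %in% names(regions)) res$region <- regions$region_id[i]
      res
    })
  })
}

#' Median-ratio copy number estimate
#'
#' Per-window ratio of alternate coverage to the mean of the reference
#' strains, summarised by the median across windows (robust to isolated
#' window artefacts), on a haploid baseline of 1.
#'
#' @inheritParams call_cnv_allele
#' @return Non-negative scalar (`NA` if no window has reference coverage).
#' @export
copy_number_estimate <- function(cov, region, alt_strain, ref_strains) {
  region <- as_tibble(as.list(region)[c("chrom", "start", "end")])
  win <- region_windows(cov, region)
  if (nrow(win) == 0) return(NA_real_)
  alt <- win[[alt_strain]]
  ref_mean <- rowMeans(as.matrix(win[, ref_strains, drop = FALSE]))
  median(ifelse(ref_mean > 0, alt / ref_mean, NA_real_), na.rm = TRUE)
}

#' Is a CNV segregating within a clonal cluster?
#'
#' A CNV segregates within a near-clonal cluster when its allele is not
#' fixed there: at least two distinct callable allele calls occur among
#' cluster members.
#'
#' @param calls Allele-call tibble (from [genotype_cnv_regions()] or with
#'   columns `strain`, `call`) for a single region.
#' @param cluster Character vector of cluster member strains.
#' @return Logical scalar.
#' @export
segregating_in_cluster <- function(calls, cluster) {
  vals <- calls$call[calls$strain %in% cluster & !is.na(calls$call)]
  dplyr::n_distinct(vals) >= 2
}
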