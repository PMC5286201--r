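#' Merge near-identical CNVs before pairwise distance counting
#'
#' When counting SV differences between strains, CNVs that are really one
#' event reported twice are collapsed first: two CNVs merge when their
#' reciprocal overlap exceeds `merge_overlap` (both overlap fractions,
#' relative to either event's span, must exceed the threshold) *and* their
#' per-strain allele calls are identical. Merging is single-linkage; one
#' representative (the first member) is kept per group.
#'
#' @param sv_geno Tibble with `id`, `type`, `chrom`, `start`, `end` plus
#'   one 0/1/NA genotype column per strain.
#' @param merge_overlap Reciprocal-overlap threshold (default 0.5).
#' @return Tibble with merged rows removed.
#' @export
merge_cnv_genotypes <- function(sv_geno, merge_overlap = 0.5) {
  strains <- setdiff(names(sv_geno),
                     c("id", "type", "chrom", "start", "end"))
  is_cnv <- sv_geno$type %in% cnv_types()
  idx <- which(is_cnv)
  if (length(idx) < 2) return(sv_geno)
  gm <- as.matrix(sv_geno[, strains, drop = FALSE])
  pairs <- t(combn(idx, 2))
  ov <- vapply(seq_len(nrow(pairs)), function(k) {
    a <- sv_geno[pairs[k, 1], ]; b <- sv_geno[pairs[k, 2], ]
    if (a$type != b$type || a$chrom != b$chrom) return(FALSE)
    inter <- min(a$end, b$end) - max(a$start, b$start) + 1
    if (inter <= 0) return(FALSE)
    fa <- inter / (a$end - a$start + 1)
    fb <- inter / (b$end - b$start + 1)
    same_geno <- identical(unname(gm[pairs[k, 1], ]), unname(gm[pairs[k, 2], ]))
    fa > merge_overlap && fb > merge_overlap && same_geno
  }, logical(1))
  g <- igraph::make_empty_graph(n = nrow(sv_geno), directed = FALSE)
  if (any(ov)) g <- igraph::add_edges(g, t(pairs[ov, , drop = FALSE]))
  comp <- igraph::components(g)$membership
  keep <- !duplicated(comp)
  sv_geno[keep, ]
}

#' Pairwise SV distance between strains
#'
#' Number of SVs at which two strains carry different alleles, counted
#' over SVs where both strains are genotyped (missing genotypes are
#' skipped per SV). CNVs are first collapsed with
#' [merge_cnv_genotypes()] so a doubly-reported event is not counted
#' twice.
#'
#' @inheritParams merge_cnv_genotypes
#' @param types Optional subset of SV types to count (e.g.
#'   `c("INV", "TRA")` for rearrangements only).
#' @return Tibble with `strain_a`, `strain_b` (a < b) and `n_diff`.
#' @export
sv_pair_distance <- function(sv_geno, merge_overlap = 0.5, types = NULL) {
  sv_geno <- merge_cnv_genotypes(sv_geno, merge_overlap)
  if (!is.null(types)) sv_geno <- filter(sv_geno, .data$type %in% types)
  strains <- setdiff(names(sv_geno),
                     c("id", "type", "chrom", "start", "end"))
  gm <- as.matrix(sv_geno[, strains, drop = FALSE])
  pairs <- t(combn(length(strains), 2))
  purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ok <- !is.na(gm[, i]) & !is.na(gm[, j])
    tibble(strain_a = strains[i], strain_b = strains[j],
           n_diff = sum(gm[ok, i] != gm[ok, j]))
  })
}

# tie-corrected Kendall tau-b via explicit concordant/discordant counting
tau_b <- function(x, y) {
  sx <- sign(outer(x, x, "-")); sy <- sign(outer(y, y, "-"))
  up <- upper.tri(sx)
  s <- sum(sx[up] * sy[up])
  n0 <- sum(up)
  n1 <- n0 - sum(sx[up] != 0)
  n2 <- n0 - sum(sy[up] != 0)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) return(NA_real_)
  s / denom
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected tau-b — distances between strains are heavily tied
#' counts, for which the uncorrected tau understates association. The
#' P value is two-sided: exact permutation enumeration for n <= 8
#' (valid with ties), otherwise the tie-corrected normal approximation.
#'
#' @param x,y Numeric vectors; pairs with a missing value are dropped.
#' @return One-row tibble: `statistic`, `estimate`, `p_value`, `n`.
#' @export
kendall_tau <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  est <- tau_b(x, y)
  if (n <= 8) {
    perms <- all_permutations(n)
    t_obs <- abs(est)
    t_perm <- apply(perms, 1, function(p) tau_b(x, y[p]))
    p <- mean(abs(t_perm) >= t_obs - 1e-12)
  } else {
    p <- suppressWarnings(
      cor.test(x, y, method = "kendall", exact = FALSE)$p.value
    )
  }
  tibble(statistic = "kendall_tau_b", estimate = est, p_value = p, n = n)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Partial Kendall rank correlation
#'
#' Correlation between `x` and `y` with the control variable `z` partialled
#' out on the tau scale:
#' `tau_xy.z = (tau_xy - tau_xz tau_yz) / sqrt((1 - tau_xz^2)(1 - tau_yz^2))`.
#' All three pairwise taus are tie-corrected (tau-b). The P value uses the
#' standard normal approximation for tau with the same variance
#' `2(2n+5) / 9n(n-1)` applied to the partial coefficient.
#'
#' @param x,y Numeric vectors.
#' @param z Control variable.
#' @return One-row tibble: `statistic`, `estimate`, `p_value`, `n`,
#'   `defined` (`FALSE`, with `NA` estimate, when a control correlation is
#'   +/-1 and the formula degenerates).
#' @export
partial_kendall <- function(x, y, z) {
  ok <- complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  t_xy <- tau_b(x, y); t_xz <- tau_b(x, z); t_yz <- tau_b(y, z)
  if (any(is.na(c(t_xy, t_xz, t_yz))) ||
      abs(t_xz) >= 1 - 1e-12 || abs(t_yz) >= 1 - 1e-12) {
    return(tibble(statistic = "partial_kendall_tau", estimate = NA_real_,
                  p_value = NA_real_, n = n, defined = FALSE))
  }
  est <- (t_xy - t_xz * t_yz) / sqrt((1 - t_xz^2) * (1 - t_yz^2))
  z_stat <- est / sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
  p <- 2 * pnorm(-abs(z_stat))
  tibble(statistic = "partial_kendall_tau", estimate = est, p_value = p,
         n = n, defined = TRUE)
}

#' Squared allelic correlation (linkage r2) between two variants
#'
#' Squared Pearson correlation of 0/1 genotype vectors over strains
#' genotyped for both variants.
#'
#' @param sv_genotypes,snp_genotypes 0/1 vectors (NA allowed).
#' @return r2 in \[0, 1\] (`NA` when either vector is constant).
#' @export
linkage_r2 <- function(sv_genotypes, snp_genotypes) {
  ok <- complete.cases(sv_genotypes, snp_genotypes)
  x <- sv_genotypes[ok]; y <- snp_genotypes[ok]
  if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Best SNP tagging per SV
#'
#' For each SV, the maximum linkage r2 over a panel of SNPs — how well the
#' SV is "tagged" by the SNP set.
#'
#' @param sv_geno SVs x strains 0/1 matrix (rownames = SV ids).
#' @param snp_geno SNPs x strains 0/1 matrix.
#' @return Tibble `sv`, `max_r2`, `best_snp`.
#' @export
linkage_scan <- function(sv_geno, snp_geno) {
  purrr::map_dfr(seq_len(nrow(sv_geno)), function(i) {
    r2 <- apply(snp_geno, 1, function(s) linkage_r2(sv_geno[i, ], s))
    best <- if (all(is.na(r2))) NA_integer_ else which.max(r2)
    tibble(
      sv = rownames(sv_geno)[i] %||% as.character(i),
      max_r2 = if (is.na(best)) NA_real_ else unname(r2[best]),
      best_snp = if (is.na(best)) NA_character_ else
        (rownames(snp_geno)[best] %||% as.character(best))
    )
  })
}

#' Reproductive-isolation correlation battery
#'
#' Given a pairwise table of crosses with genetic distances and offspring
#' viability, computes the Kendall correlation of each distance with
#' viability and the two partial correlations (SNPs controlling for
#' rearrangements and vice versa), mirroring the standard analysis of
#' intrinsic reproductive isolation.
#'
#' @param pairs Tibble with columns `viability` and any of `n_snp_diff`,
#'   `n_sv_diff`, `n_rearrangement_diff`, `n_cnv_diff`.
#' @return Tidy tibble of correlation results (one row per statistic).
#' @export
isolation_correlations <- function(pairs) {
  out <- list()
  for (col in intersect(c("n_snp_diff", "n_sv_diff", "n_rearrangement_diff",
                          "n_cnv_diff"), names(pairs))) {
    out[[length(out) + 1]] <- mutate(
      kendall_tau(pairs[[col]], pairs$viability),
      term = paste0(col, " ~ viability"), .before = 1)
  }
  if (all(c("n_snp_diff", "n_rearrangement_diff") %in% names(pairs))) {
    out[[length(out) + 1]] <- mutate(
      partial_kendall(pairs$n_snp_diff, pairs$viability,
                      pairs$n_rearrangement_diff),
      term = "n_snp_diff ~ viability | rearrangements", .before = 1)
    out[[length(out) + 1]] <- mutate(
      partial_kendall(pairs$n_rearrangement_diff, pairs$viability,
                      pairs$n_snp_diff),
      term = "n_rearrangement_diff ~ viability | SNPs", .before = 1)
  }
  bind_rows(out)
}
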