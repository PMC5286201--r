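#' Extract SNPs flanking a CNV region
#'
#' Keeps genotyped sites whose position lies in the 20-kb (by default)
#' flanks of the region: `[start - flank, start)` upstream union
#' `(end, end + flank]` downstream, clipped at position 1 and at the
#' chromosome end when known. A CNV with no SNPs in its flanks returns an
#' empty tibble flagged with attribute `no_snps = TRUE` (this happens for
#' real data, e.g. a mitochondrial CNV spanning nearly the whole molecule).
#'
#' @param snps Genotype tibble: `chrom`, `pos` plus one 0/1 (or dosage)
#'   column per strain, one row per site.
#' @param region One-row data frame/list with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param flank_bp Flank width in bp (default 20000).
#' @param chrom_length Optional chromosome length for downstream clipping.
#' @return Tibble of the retained sites (attribute `no_snps` when empty).
#' @export
extract_flank_snps <- function(snps, region, flank_bp = 20000,
                               chrom_length = NULL) {
  region <- as.list(region)
  lo <- max(1, region$start - flank_bp)
  hi <- region$end + flank_bp
  if (!is.null(chrom_length)) hi <- min(hi, chrom_length)
  out <- filter(snps, .data$chrom == region$chrom,
                (.data$pos >= lo & .data$pos < region$start) |
                  (.data$pos > region$end & .data$pos <= hi))
  if (nrow(out) == 0) attr(out, "no_snps") <- TRUE
  out
}

strain_cols <- function(tbl) setdiff(names(tbl), c("chrom", "pos"))

#' Normalized Hamming distance between strains from SNP genotypes
#'
#' Pairwise fraction of differing genotypes over sites where both strains
#' are non-missing. Strain pairs sharing no genotyped site get `NA`.
#'
#' @param snps Genotype tibble (`chrom`, `pos`, strain columns) or a
#'   sites x strains numeric matrix.
#' @return Symmetric distance matrix with strain dimnames.
#' @export
snp_distance <- function(snps) {
  g <- if (is.matrix(snps)) snps else
    as.matrix(snps[, strain_cols(snps), drop = FALSE])
  ns <- ncol(g)
  d <- matrix(0, ns, ns, dimnames = list(colnames(g), colnames(g)))
  for (i in seq_len(ns)) {
    for (j in seq_len(i)) {
      shared <- !is.na(g[, i]) & !is.na(g[, j])
      d[i, j] <- d[j, i] <-
        if (any(shared)) mean(g[shared, i] != g[shared, j]) else NA_real_
    }
  }
  diag(d) <- 0
  d
}

#' Euclidean distance between strains from copy numbers
#'
#' @param cn Copy-number tibble: `strain` column plus one numeric column
#'   per CNV region.
#' @param regions Optional character vector selecting region columns.
#' @return Symmetric Euclidean distance matrix over the selected regions.
#' @export
copy_number_distance <- function(cn, regions = NULL) {
  m <- as.matrix(cn[, regions %||% setdiff(names(cn), "strain"), drop = FALSE])
  rownames(m) <- cn$strain
  as.matrix(dist(m, method = "euclidean"))
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour joining (Saitou-Nei Q criterion, via [ape::nj()]),
#' followed by clamping of negative branch lengths: a negative edge is set
#' to zero and its deficit transferred to the sister edge, preserving the
#' total branch length. For exactly two taxa the single split is returned
#' with the distance shared equally between the two pendant edges.
#'
#' @param d Symmetric numeric matrix (zero diagonal) with taxon dimnames;
#'   the triangle inequality is not required.
#' @return An [ape] `phylo` tree (unrooted for >= 3 taxa).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2) abort("nj_tree(): need at least 2 taxa",
                         class = "svkit_parameter_error")
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    abort("nj_tree(): distance matrix must be symmetric",
          class = "svkit_parameter_error")
  }
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (nrow(d) == 2) {
    tree <- list(
      edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
      edge.length = rep(d[1, 2] / 2, 2),
      tip.label = rownames(d), Nnode = 1L
    )
    class(tree) <- "phylo"
    return(tree)
  }
  tree <- ape::nj(d)
  clamp_negative_branches(tree)
}

# negative edge -> 0; deficit moved to a sister edge (same parent node)
clamp_negative_branches <- function(tree) {
  el <- tree$edge.length
  parent <- tree$edge[, 1]
  for (i in order(el)) {
    if (el[i] >= 0) next
    sibs <- setdiff(which(parent == parent[i]), i)
    if (length(sibs) > 0) {
      el[sibs[1]] <- el[sibs[1]] + el[i]
    }
    el[i] <- 0
  }
  tree$edge.length <- pmax(el, 0)
  tree
}

#' Total branch length of a tree
#'
#' Sum of all edge lengths; invariant to rooting.
#'
#' @param tree A `phylo` tree.
#' @return Non-negative scalar.
#' @export
total_branch_length <- function(tree) sum(tree$edge.length)

#' Normalize branch lengths to their maximum
#'
#' @param x Numeric vector of (total) branch lengths.
#' @return `x / max(x)`; all zero stays all zero.
#' @export
normalize_branch_lengths <- function(x) {
  mx <- max(x, na.rm = TRUE)
  if (mx == 0) x else x / mx
}

#' Relative transience of a CNV within a clonal cluster
#'
#' The relative transience of a CNV in a near-clonal cluster is the ratio
#' `sigma_rc = sigma_ic / sigma_oc` of the within-cluster standard
#' deviation of its copy number to the standard deviation across all
#' strains outside the cluster (sample SD, n-1 denominator). High values
#' mark CNVs that churn inside a clonal population faster than they vary
#' across the rest of the population. When the outside SD is zero the
#' statistic is undefined and reported as `NA` with `defined = FALSE`,
#' never as infinity.
#'
#' @param cn Copy-number tibble (`strain` plus region columns).
#' @param region Region column name.
#' @param cluster Character vector of cluster member strains (>= 2; at
#'   least 2 strains must remain outside).
#' @return One-row tibble: `region`, `n_in`, `n_out`, `sigma_ic`,
#'   `sigma_oc`, `sigma_rc`, `defined`.
#' @export
relative_transience <- function(cn, region, cluster) {
  inside <- cn[[region]][cn$strain %in% cluster]
  outside <- cn[[region]][!cn$strain %in% cluster]
  if (length(inside) < 2 || length(outside) < 2) {
    abort("relative_transience(): need >= 2 strains inside and outside the cluster",
          class = "svkit_parameter_error")
  }
  s_ic <- sd(inside)
  s_oc <- sd(outside)
  defined <- s_oc > 0
  tibble(
    region = region, n_in = length(inside), n_out = length(outside),
    sigma_ic = s_ic, sigma_oc = s_oc,
    sigma_rc = if (defined) s_ic / s_oc else NA_real_,
    defined = defined
  )
}

#' Per-CNV transience table
#'
#' For every CNV region and every cluster: the relative-transience
#' statistic plus the total branch lengths of the per-CNV copy-number
#' tree (neighbour joining on per-region Euclidean distances) and, when
#' SNP genotypes are supplied, of the flank-SNP tree (neighbour joining on
#' normalized Hamming distances). Branch lengths are normalized to their
#' maximum across CNVs within each tree kind.
#'
#' @param cn Copy-number tibble (`strain` plus region columns).
#' @param clusters Tibble with `strain`, `cluster` assigning (a subset of)
#'   strains to near-clonal clusters.
#' @param snps Optional genotype tibble for flank-SNP trees.
#' @param region_coords Optional tibble `region`, `chrom`, `start`, `end`
#'   locating each region column (required with `snps`).
#' @param flank_bp Flank width for SNP extraction.
#' @return Tibble, one row per region x cluster, with `sigma_*` columns
#'   and normalized branch lengths (`cnv_bl_norm`, `snp_bl_norm`).
#' @export
transience_table <- function(cn, clusters, snps = NULL, region_coords = NULL,
                             flank_bp = 20000) {
  regions <- setdiff(names(cn), "strain")
  cnv_bl <- vapply(regions, function(r) {
    total_branch_length(nj_tree(copy_number_distance(cn, r)))
  }, numeric(1))
  snp_bl <- rep(NA_real_, length(regions))
  names(snp_bl) <- regions
  if (!is.null(snps)) {
    if (is.null(region_coords)) {
      abort("transience_table(): region_coords required when snps are given")
    }
    for (r in regions) {
      rc <- filter(region_coords, .data$region == r)
      if (nrow(rc) == 0) next
      fl <- extract_flank_snps(snps, rc[1, ], flank_bp)
      if (nrow(fl) == 0) next
      dm <- snp_distance(fl)
      dm <- dm[cn$strain, cn$strain]
      snp_bl[r] <- total_branch_length(nj_tree(dm))
    }
  }
  cnv_norm <- normalize_branch_lengths(cnv_bl)
  snp_norm <- if (all(is.na(snp_bl))) snp_bl else
    snp_bl / max(snp_bl, na.rm = TRUE)
  purrr::map_dfr(unique(clusters$cluster), function(cl) {
    members <- clusters$strain[clusters$cluster == cl]
    purrr::map_dfr(regions, function(r) {
      mutate(relative_transience(cn, r, members), cluster = cl,
             cnv_branch_length = cnv_bl[[r]], cnv_bl_norm = cnv_norm[[r]],
             snp_bl_norm = snp_norm[[r]], .after = 1)
    })
  })
}

#' Association between copy-number spread and tree length
#'
#' Spearman rank correlation (average ranks for ties) between a vector of
#' per-CNV total branch lengths and per-CNV copy-number standard
#' deviations.
#'
#' @param branch_lengths,cn_sd Numeric vectors of equal length.
#' @return One-row tibble: `statistic`, `estimate`, `p_value`, `n`.
#' @export
branch_length_association <- function(branch_lengths, cn_sd) {
  ok <- complete.cases(branch_lengths, cn_sd)
  ct <- suppressWarnings(cor.test(branch_lengths[ok], cn_sd[ok],
                                  method = "spearman", exact = FALSE))
  tibble(statistic = "spearman_rho", estimate = unname(ct$estimate),
         p_value = ct$p.value, n = sum(ok))
}

#' Scatterplot of SNP- versus CNV-tree branch lengths
#'
#' @param tbl Output of [transience_table()] (needs `snp_bl_norm` and
#'   `cnv_bl_norm`).
#' @return A ggplot.
#' @export
plot_transience <- function(tbl) {
  df <- distinct(tbl, .data$region, .data$snp_bl_norm, .data$cnv_bl_norm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snp_bl_norm, y = .data$cnv_bl_norm)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "SNP-tree branch length (normalized)",
                  y = "CNV-tree branch length (normalized)",
                  title = "Local SNP divergence vs copy-number divergence") +
    ggplot2::theme_minimal()
}
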