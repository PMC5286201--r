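sv_geno_fixture <- function() {
  tibble::tibble(
    id = paste0("sv", 1:4),
    type = c("DUP", "DUP", "DEL", "INV"),
    chrom = "I",
    start = c(1000L, 1500L, 9000L, 20000L),
    end = c(2000L, 2100L, 9500L, 21000L),
    s1 = c(1L, 1L, 0L, 0L),
    s2 = c(1L, 1L, 1L, 0L),
    s3 = c(0L, 0L, 1L, 1L)
  )
}

test_that("CNVs with >50% reciprocal overlap and identical alleles merge", {
  # sv1 1000-2000 (1001 bp), sv2 1500-2100 (601 bp): intersection 501 bp ->
  # 50.05% of sv1, 83% of sv2: reciprocal overlap > 0.5, identical alleles
  g <- sv_geno_fixture()
  merged <- merge_cnv_genotypes(g, 0.5)
  expect_equal(nrow(merged), 3)
  expect_true("sv1" %in% merged$id)
  expect_false("sv2" %in% merged$id)
  # shrink sv2 to 1600-2100: intersection 401/1001 = 40% of sv1 -> no merge
  g2 <- g
  g2$start[2] <- 1600L
  expect_equal(nrow(merge_cnv_genotypes(g2, 0.5)), 4)
  # same span but different allele vectors: never merged
  g3 <- g
  g3$s3[2] <- 1L
  expect_equal(nrow(merge_cnv_genotypes(g3, 0.5)), 4)
  # non-CNV types are never merged
  g4 <- g
  g4$type[1:2] <- "INV"
  expect_equal(nrow(merge_cnv_genotypes(g4, 0.5)), 4)
})

test_that("pairwise SV distance counts differing genotyped alleles", {
  g <- sv_geno_fixture()
  d <- sv_pair_distance(g)
  get <- function(a, b) d$n_diff[d$strain_a == a & d$strain_b == b]
  # sv1/sv2 collapse to one CNV first, so s2-s3 differ at the merged CNV,
  # at sv4, and nowhere else
  expect_equal(get("s1", "s2"), 1)  # differ at sv3 only
  expect_equal(get("s1", "s3"), 3)
  expect_equal(get("s2", "s3"), 2)
  # identical strains -> 0; missing genotypes skipped per SV
  g$s4 <- g$s1
  g$s5 <- c(NA, 0L, 0L, 0L)
  d2 <- sv_pair_distance(g)
  expect_equal(d2$n_diff[d2$strain_a == "s1" & d2$strain_b == "s4"], 0)
  expect_equal(d2$n_diff[d2$strain_a == "s1" & d2$strain_b == "s5"], 1)
  # type restriction counts rearrangements only
  d3 <- sv_pair_distance(g, types = c("INV", "TRA"))
  expect_equal(d3$n_diff[d3$strain_a == "s1" & d3$strain_b == "s3"], 1)
})

test_that("pairwise SV distance is a pseudometric on complete data", {
  set.seed(120)
  g <- tibble::tibble(
    id = paste0("sv", 1:12), type = "INV", chrom = "I",
    start = seq(1000L, by = 5000L, length.out = 12),
    end = seq(2000L, by = 5000L, length.out = 12)
  )
  for (s in paste0("s", 1:5)) g[[s]] <- sample(0:1, 12, replace = TRUE)
  d <- sv_pair_distance(g)
  dm <- matrix(0, 5, 5, dimnames = list(paste0("s", 1:5), paste0("s", 1:5)))
  for (k in seq_len(nrow(d))) {
    dm[d$strain_a[k], d$strain_b[k]] <- dm[d$strain_b[k], d$strain_a[k]] <- d$n_diff[k]
  }
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    expect_lte(dm[i, j], dm[i, k] + dm[k, j])
  }
})

test_that("Kendall tau-b hits the exact bounds and matches pair enumeration", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(kendall_tau(x, x)$estimate, 1)
  expect_equal(kendall_tau(x, -x)$estimate, -1)
  # O(n^2) concordant/discordant enumeration oracle (tie-corrected)
  set.seed(121)
  for (i in 1:10) {
    a <- rpois(12, 4); b <- rpois(12, 4)
    conc <- disc <- 0
    for (p in 1:11) for (q in (p + 1):12) {
      s <- sign(a[p] - a[q]) * sign(b[p] - b[q])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
    n0 <- choose(12, 2)
    tx <- sum(sapply(split(seq_along(a), a), function(ix) choose(length(ix), 2)))
    ty <- sum(sapply(split(seq_along(b), b), function(ix) choose(length(ix), 2)))
    tau_oracle <- (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
    res <- kendall_tau(a, b)
    expect_equal(res$estimate, tau_oracle, tolerance = 1e-12)
    # estimate agrees with the standard implementation
    expect_equal(res$estimate,
                 unname(suppressWarnings(cor.test(a, b, method = "kendall")$estimate)),
                 tolerance = 1e-12)
  }
})

test_that("small-sample Kendall P comes from exact permutation enumeration", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1, 3, 2, 5, 4)
  res <- kendall_tau(x, y)
  # tie-free n=5: exact two-sided P equals cor.test's exact value
  ref <- cor.test(x, y, method = "kendall", exact = TRUE)$p.value
  expect_equal(res$p_value, ref, tolerance = 1e-12)
})

test_that("partial Kendall collapses to tau when controls are uncorrelated", {
  # z constant-free and independent by construction: tau_xz = tau_yz = 0
  x <- c(1, 2, 3, 4)
  y <- c(1, 3, 2, 4)
  z <- c(1, -1, -1, 1)  # tau(x,z) = 0, tau(y,z) = 0
  pk <- partial_kendall(x, y, z)
  expect_equal(pk$estimate, kendall_tau(x, y)$estimate, tolerance = 1e-12)
  # direct formula evaluation from the three pairwise taus
  set.seed(122)
  a <- rnorm(20); b <- rnorm(20); c_ <- rnorm(20)
  t_ab <- kendall_tau(a, b)$estimate
  t_ac <- kendall_tau(a, c_)$estimate
  t_bc <- kendall_tau(b, c_)$estimate
  expect_equal(partial_kendall(a, b, c_)$estimate,
               (t_ab - t_ac * t_bc) / sqrt((1 - t_ac^2) * (1 - t_bc^2)),
               tolerance = 1e-12)
  # degenerate control: |tau_xz| = 1 -> undefined, flagged
  deg <- partial_kendall(1:10, rnorm(10), 1:10)
  expect_false(deg$defined)
  expect_true(is.na(deg$estimate))
})

test_that("partialling a shared driver attenuates the marginal correlation", {
  set.seed(123)
  shrunk <- 0
  for (i in 1:100) {
    z <- rnorm(60)
    x <- z + rnorm(60, 0, 0.6)
    y <- z + rnorm(60, 0, 0.6)
    if (abs(partial_kendall(x, y, z)$estimate) <
        abs(kendall_tau(x, y)$estimate)) {
      shrunk <- shrunk + 1
    }
  }
  expect_gte(shrunk, 95)
})

test_that("linkage r2 spans its bounds and vanishes for independent variants", {
  g <- c(0, 1, 0, 1, 1, 0, 1, 0)
  expect_equal(linkage_r2(g, g), 1.0)
  expect_equal(linkage_r2(g, 1 - g), 1.0)
  set.seed(124)
  a <- rbinom(1000, 1, 0.5); b <- rbinom(1000, 1, 0.5)
  expect_lt(linkage_r2(a, b), 0.02)
  expect_true(is.na(linkage_r2(rep(1, 8), g)))
  # scan reports the best-tagging SNP per SV
  svm <- matrix(c(g, 1 - g), 2, byrow = TRUE,
                dimnames = list(c("sv1", "sv2"), NULL))
  snpm <- matrix(c(g, rbinom(8, 1, 0.5)), 2, byrow = TRUE,
                 dimnames = list(c("snpA", "snpB"), NULL))
  scan <- linkage_scan(svm, snpm)
  expect_equal(scan$max_r2, c(1, 1))
  expect_equal(scan$best_snp, c("snpA", "snpA"))
})

test_that("isolation battery reports marginal and partial correlations", {
  set.seed(125)
  n <- 58
  snp <- runif(n); rea <- runif(n); cnv <- runif(n)
  viability <- pmin(1, pmax(0, 0.9 - 0.4 * snp - 0.4 * rea + rnorm(n, 0, 0.08)))
  pairs <- tibble::tibble(
    strain_a = paste0("p", 1:n), strain_b = paste0("q", 1:n),
    n_snp_diff = rank(snp), n_rearrangement_diff = rank(rea),
    n_cnv_diff = rank(cnv), viability = viability
  )
  res <- isolation_correlations(pairs)
  expect_true(all(c("n_snp_diff ~ viability",
                    "n_rearrangement_diff ~ viability",
                    "n_cnv_diff ~ viability",
                    "n_snp_diff ~ viability | rearrangements",
                    "n_rearrangement_diff ~ viability | SNPs") %in% res$term))
  expect_true(all(abs(res$estimate) <= 1, na.rm = TRUE))
  # informative distances correlate negatively; uninformative CNV does not
  expect_lt(res$estimate[res$term == "n_snp_diff ~ viability"], 0)
  expect_gt(res$p_value[res$term == "n_cnv_diff ~ viability"], 0.05)
})
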