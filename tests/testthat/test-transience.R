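test_that("flank-SNP extraction respects the boundary conventions", {
  snps <- geno_tbl(matrix(0L, 6, 2, dimnames = list(NULL, c("s1", "s2"))),
                   pos = c(100L, 5000L, 25000L, 30000L, 45000L, 70000L))
  region <- list(chrom = "chr1", start = 25000, end = 40000)
  out <- extract_flank_snps(snps, region, flank_bp = 20000)
  # in-region site (25000, 30000) excluded; 5000 = start - flank included;
  # 45000 in downstream flank; 70000 beyond end + flank (60000) excluded;
  # 100 below start - flank excluded
  expect_equal(out$pos, c(5000L, 45000L))
  # flank 0 -> empty, flagged
  none <- extract_flank_snps(snps, region, flank_bp = 0)
  expect_equal(nrow(none), 0)
  expect_true(isTRUE(attr(none, "no_snps")))
  # chromosome-end clipping
  clipped <- extract_flank_snps(snps, region, flank_bp = 20000,
                                chrom_length = 44000)
  expect_equal(nrow(clipped), 1)
})

test_that("SNP distance is the normalized Hamming distance over shared sites", {
  g <- matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
                1, 1, 1, 1, 1, 1, 1, 1, 1, 1), 10, 2,
              dimnames = list(NULL, c("a", "b")))
  d <- snp_distance(g)
  expect_equal(d["a", "b"], 1.0)
  expect_equal(d["a", "a"], 0)
  # brute-force oracle with missing data
  set.seed(110)
  g2 <- matrix(sample(c(0L, 1L, NA), 200, replace = TRUE,
                      prob = c(.45, .45, .1)), 40, 5,
               dimnames = list(NULL, paste0("s", 1:5)))
  d2 <- snp_distance(g2)
  for (i in 1:5) {
    for (j in 1:5) {
      sh <- !is.na(g2[, i]) & !is.na(g2[, j])
      expect_equal(d2[i, j], mean(g2[sh, i] != g2[sh, j]))
    }
  }
  expect_true(isSymmetric(d2))
})

test_that("copy-number distance is Euclidean over selected regions", {
  cn <- tibble::tibble(strain = c("a", "b"), r1 = c(1, 4), r2 = c(1, 5))
  d <- copy_number_distance(cn)
  expect_equal(d["a", "b"], 5)  # 3-4-5 triangle
  expect_equal(unname(diag(d)), c(0, 0))
  # oracle on random matrices
  set.seed(111)
  cn2 <- tibble::tibble(strain = paste0("s", 1:6))
  for (r in paste0("r", 1:4)) cn2[[r]] <- runif(6, 0, 4)
  m <- as.matrix(cn2[, -1]); rownames(m) <- cn2$strain
  expect_equal(copy_number_distance(cn2), as.matrix(dist(m)))
})

test_that("two-taxon trees carry the full distance as total branch length", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  tr <- nj_tree(d)
  expect_equal(total_branch_length(tr), 0.4)
  expect_setequal(tr$tip.label, c("a", "b"))
  expect_error(nj_tree(matrix(0, 1, 1)), class = "svkit_parameter_error")
  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(asym), class = "svkit_parameter_error")
})

test_that("neighbour joining exactly recovers additive distances", {
  set.seed(112)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    ref <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(ref)
    tr <- nj_tree(d)
    # path distances and total branch length reproduced exactly
    expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
    expect_equal(total_branch_length(tr), sum(ref$edge.length),
                 tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(ref), tr), 0,
                 ignore_attr = TRUE)
  }
})

test_that("ultrametric star distances give equal terminal edges d/2", {
  n <- 5
  d <- matrix(1, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
  diag(d) <- 0
  tr <- nj_tree(d)
  term <- tr$edge.length[tr$edge[, 2] <= n]
  expect_equal(term, rep(0.5, n), tolerance = 1e-8)
  internal <- tr$edge.length[tr$edge[, 2] > n]
  expect_equal(internal, rep(0, length(internal)), tolerance = 1e-8)
})

test_that("negative NJ branches are clamped with total length preserved", {
  # non-additive matrix known to produce a negative NJ edge
  d <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 0.1,
                3, 3, 0.1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  raw <- ape::nj(d)
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  expect_equal(total_branch_length(tr), sum(raw$edge.length), tolerance = 1e-10)
})

test_that("total branch length is input-order invariant and normalizer scales", {
  set.seed(113)
  cn <- tibble::tibble(strain = paste0("s", 1:8), r1 = runif(8, 0, 4),
                       r2 = runif(8, 0, 4))
  t1 <- total_branch_length(nj_tree(copy_number_distance(cn)))
  perm <- cn[sample(8), ]
  t2 <- total_branch_length(nj_tree(copy_number_distance(perm)))
  expect_equal(t1, t2, tolerance = 1e-8)
  expect_equal(normalize_branch_lengths(c(2, 4, 8)), c(0.25, 0.5, 1.0))
})

test_that("relative transience matches hand arithmetic and handles degeneracy", {
  cn <- tibble::tibble(
    strain = paste0("s", 1:10),
    r1 = c(1, 1, 2, 2, 1, 3, 1, 3, 1, 3)
  )
  cluster <- paste0("s", 1:4)   # inside {1,1,2,2}; outside {1,3,1,3,1,3}
  res <- relative_transience(cn, "r1", cluster)
  expect_equal(res$sigma_ic, sd(c(1, 1, 2, 2)))
  expect_equal(res$sigma_oc, sd(c(1, 3, 1, 3, 1, 3)))
  expect_equal(res$sigma_rc, 0.527, tolerance = 1e-3)
  # constant inside -> 0
  cn$r2 <- c(2, 2, 2, 2, 1, 4, 0, 2, 1, 5)
  expect_equal(relative_transience(cn, "r2", cluster)$sigma_rc, 0)
  # constant outside -> undefined, flagged, not infinite
  cn$r3 <- c(1, 2, 1, 2, 1, 1, 1, 1, 1, 1)
  res3 <- relative_transience(cn, "r3", cluster)
  expect_false(res3$defined)
  expect_true(is.na(res3$sigma_rc))
  expect_error(relative_transience(cn, "r1", "s1"),
               class = "svkit_parameter_error")
})

test_that("sigma_rc is scale invariant and near 1 under exchangeability", {
  set.seed(114)
  cn <- tibble::tibble(strain = paste0("s", 1:30), r1 = rnorm(30, 2, 0.7))
  cluster <- paste0("s", 1:10)
  base <- relative_transience(cn, "r1", cluster)$sigma_rc
  cn$r1 <- cn$r1 * 7.3
  expect_equal(relative_transience(cn, "r1", cluster)$sigma_rc, base,
               tolerance = 1e-12)
  # inside and outside drawn from one distribution: sigma_rc ~ 1 on average
  ratios <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    v <- rnorm(30, 2, 0.7)
    sd(v[1:10]) / sd(v[11:30])
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.1)
})

test_that("transience table links sigma_rc with per-CNV tree lengths", {
  pop <- synth_clonal_population(n_clusters = 4, strains_per_cluster = 4,
                                 n_cnvs = 8, n_snps = 300,
                                 cnv_gain_loss_rate = 0.15, seed = 115)
  tt <- transience_table(pop$cn, pop$clusters)
  expect_equal(nrow(tt), 8 * 4)
  expect_true(all(tt$sigma_rc[tt$defined] >= 0))
  expect_true(max(tt$cnv_bl_norm) == 1)
  p <- plot_transience(tt)
  expect_s3_class(p, "ggplot")
})

test_that("gain/loss rate zero fixes every CNV within every cluster", {
  pop <- synth_clonal_population(n_clusters = 3, strains_per_cluster = 5,
                                 n_cnvs = 10, cnv_gain_loss_rate = 0,
                                 seed = 116)
  tt <- transience_table(pop$cn, pop$clusters)
  expect_true(all(tt$sigma_ic == 0))
  expect_true(all(tt$sigma_rc[tt$defined] == 0))
})

test_that("Spearman association matches cor.test with tied ranks", {
  set.seed(117)
  x <- rpois(40, 5); y <- x + rpois(40, 2)
  res <- branch_length_association(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(res$estimate, unname(ref$estimate))
  expect_equal(res$p_value, ref$p.value)
})
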