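#' Generate a random genome
#'
#' IID nucleotide sequences at a given GC content (default 0.36, typical
#' of the fission-yeast nuclear genome). Deterministic for a fixed seed.
#'
#' @param chrom_lengths Named (or unnamed) vector of chromosome lengths in
#'   bp; unnamed chromosomes are called `chr1`, `chr2`, ...
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed.
#' @return Named character vector of sequences.
#' @export
random_genome <- function(chrom_lengths, gc = 0.36, seed = NULL) {
  local_seed(seed)
  if (length(chrom_lengths) == 0) return(stats::setNames(character(0), character(0)))
  nms <- names(chrom_lengths) %||% paste0("chr", seq_along(chrom_lengths))
  if (is.null(names(chrom_lengths))) names(chrom_lengths) <- nms
  out <- vapply(chrom_lengths, function(L) {
    if (L == 0) return("")
    random_sequence(L, gc = gc)
  }, character(1))
  stats::setNames(out, names(chrom_lengths))
}

#' Mock caller error profile
#'
#' Three-parameter error model for a simulated SV caller: per-event
#' detection probability, breakpoint jitter, and a count of uniformly
#' placed false positives. Emulates the per-caller error structure seen
#' when benchmarking real callers on simulated genomes.
#'
#' @param sensitivity Detection probability in \[0, 1\].
#' @param n_false_positives Number of false-positive calls to add.
#' @param jitter_sd Breakpoint jitter SD in bp (rounded Gaussian,
#'   truncated at +/- 3 SD so that jittered calls stay inside the match
#'   tolerance whenever `jitter_sd <= tolerance/3`).
#' @param label Caller label.
#' @param pe_range Range from which paired-end support is drawn uniformly.
#' @return List of class `mock_caller_profile`.
#' @export
mock_caller_profile <- function(sensitivity = 0.8, n_false_positives = 0,
                                jitter_sd = 150, label = "mock",
                                pe_range = c(11, 60)) {
  if (sensitivity < 0 || sensitivity > 1) {
    abort("mock_caller_profile(): sensitivity must lie in [0, 1]")
  }
  if (n_false_positives < 0 || jitter_sd < 0) {
    abort("mock_caller_profile(): n_false_positives and jitter_sd must be >= 0")
  }
  structure(list(sensitivity = sensitivity,
                 n_false_positives = as.integer(n_false_positives),
                 jitter_sd = jitter_sd, label = label, pe_range = pe_range),
            class = "mock_caller_profile")
}

trunc_jitter <- function(n, sd) {
  if (sd == 0) return(rep(0L, n))
  as.integer(round(pmin(pmax(rnorm(n, 0, sd), -3 * sd), 3 * sd)))
}

#' Simulate an error-prone caller on a truth set
#'
#' Each truth event is reported independently with probability
#' `profile$sensitivity`; reported breakpoints are jittered by truncated
#' rounded Gaussian noise. `n_false_positives` additional calls of random
#' type and size are placed uniformly on the genome, rejecting positions
#' within 1 kb of any truth event, so false positives never accidentally
#' match truth.
#'
#' @param truth Truth tibble.
#' @param profile A [mock_caller_profile()].
#' @param genome Named character vector of sequences, or a named numeric
#'   vector of chromosome lengths (sequence content is not needed).
#' @param seed Integer seed.
#' @return Tibble of SV calls labelled with `profile$label`.
#' @export
mock_caller <- function(truth, profile, genome, seed = NULL) {
  local_seed(seed)
  truth <- truth_records(truth)
  lens <- genome_lengths(genome)
  calls <- list()
  detected <- which(runif(nrow(truth)) < profile$sensitivity)
  if (length(detected) > 0) {
    tt <- truth[detected, ]
    k <- nrow(tt)
    j1 <- trunc_jitter(k, profile$jitter_sd)
    j2 <- trunc_jitter(k, profile$jitter_sd)
    start <- pmax(1L, tt$start + j1)
    is_point <- tt$type %in% c("INS", "TRA")
    end <- ifelse(is_point, start, pmax(start, tt$end + j2))
    pos2 <- ifelse(tt$type == "TRA", pmax(1L, tt$pos2 + j2), NA_integer_)
    calls[[1]] <- tibble(
      id = paste0(profile$label, "_", tt$id), type = tt$type,
      chrom = tt$chrom, start = as.integer(start), end = as.integer(end),
      chrom2 = ifelse(tt$type == "TRA", tt$chrom2, NA_character_),
      pos2 = as.integer(pos2),
      length = ifelse(is_point, NA_integer_, as.integer(end - start + 1L)),
      pe_support = as.integer(sample(seq(profile$pe_range[1],
                                         profile$pe_range[2]), k,
                                     replace = TRUE))
    )
  }
  if (profile$n_false_positives > 0) {
    fp <- place_false_positives(profile$n_false_positives, truth, lens)
    fp$pe_support <- as.integer(sample(seq(profile$pe_range[1],
                                           profile$pe_range[2]),
                                       nrow(fp), replace = TRUE))
    fp$id <- paste0(profile$label, "_fp", seq_len(nrow(fp)))
    calls[[length(calls) + 1]] <- fp
  }
  out <- if (length(calls)) bind_rows(calls) else empty_sv_tbl()
  out$caller <- profile$label
  sv_calls(arrange(out, .data$chrom, .data$start), caller = profile$label)
}

place_false_positives <- function(n_fp, truth, lens, guard = 1000) {
  rows <- vector("list", n_fp)
  for (i in seq_len(n_fp)) {
    for (try in seq_len(1000)) {
      ty <- sample(c("DEL", "DUP", "INS", "INV"), 1)
      len <- if (ty == "INS") 1L else sample(100:10000, 1)
      chrom <- sample(names(lens), 1, prob = lens)
      hi <- lens[[chrom]] - len
      if (hi < 1) next
      s <- sample.int(hi, 1)
      e <- if (ty == "INS") s else s + len - 1L
      near <- truth$chrom == chrom &
        truth$start - guard <= e + guard & s - guard <= truth$end + guard
      if (any(near)) next
      rows[[i]] <- tibble(
        id = NA_character_, type = ty, chrom = chrom, start = as.integer(s),
        end = as.integer(e), chrom2 = NA_character_, pos2 = NA_integer_,
        length = if (ty == "INS") NA_integer_ else as.integer(len),
        pe_support = NA_integer_
      )
      break
    }
    if (is.null(rows[[i]])) {
      abort("mock_caller(): could not place false positives away from truth")
    }
  }
  bind_rows(rows)
}

#' Synthesize a windowed coverage matrix with known copy numbers
#'
#' Per-window read counts with mean `depth x copy_number`, drawn Poisson
#' (default) or negative binomial for over-dispersed coverage. The default
#' depth of 40 reads per window mirrors 40x short-read coverage with
#' 100-bp windows.
#'
#' @param regions Tibble `region_id`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param true_copy_numbers Strains x regions numeric matrix (rownames =
#'   strains, colnames = region_ids); 1 = reference dosage.
#' @param depth Mean reads per window at copy number 1.
#' @param noise `"poisson"` or `"negbin"`.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   over-dispersed); only with `noise = "negbin"`.
#' @param window_width Window width in bp (default 100).
#' @param seed Integer seed.
#' @return Coverage tibble (`chrom`, `start`, `end` 0-based half-open,
#'   plus one column per strain).
#' @export
synth_coverage <- function(regions, true_copy_numbers, depth = 40,
                           noise = c("poisson", "negbin"), dispersion = 10,
                           window_width = 100, seed = NULL) {
  noise <- match.arg(noise)
  local_seed(seed)
  regions <- as_tibble(regions)
  strains <- rownames(true_copy_numbers)
  win <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    starts <- seq(r$start - 1L, r$end - window_width, by = window_width)
    tibble(region_id = r$region_id, chrom = r$chrom,
           start = as.integer(starts),
           end = as.integer(starts + window_width))
  })
  for (s in strains) {
    mu <- depth * true_copy_numbers[s, win$region_id]
    win[[s]] <- if (noise == "poisson") rpois(nrow(win), mu) else
      rnbinom(nrow(win), mu = mu, size = dispersion)
  }
  select(win, -"region_id")
}

#' Synthesize a clonal population with transient CNVs
#'
#' Builds near-clonal clusters of strains: cluster founders are assigned
#' independent SNP haplotypes and CNV copy-number states; members inherit
#' the founder state, flip each CNV with probability
#' `cnv_gain_loss_rate` to a different state (producing segregating CNVs),
#' and accumulate at most `max_cluster_snp_diff / 2` private SNP
#' mutations, so within-cluster pairwise SNP distances stay below the
#' ceiling by construction.
#'
#' @param n_clusters Number of near-clonal clusters.
#' @param strains_per_cluster Strains per cluster.
#' @param n_cnvs Number of CNV regions.
#' @param n_snps Number of SNP sites.
#' @param cnv_gain_loss_rate Per-member, per-CNV state-flip probability.
#' @param max_cluster_snp_diff Ceiling on within-cluster pairwise SNP
#'   differences (default 150, the near-clonal criterion).
#' @param cn_states Copy-number states sampled for founders and flips.
#' @param seed Integer seed.
#' @return List with `cn` (copy-number tibble: `strain` + region columns),
#'   `snps` (genotype tibble: `chrom`, `pos`, strain columns),
#'   `clusters` (tibble `strain`, `cluster`).
#' @export
synth_clonal_population <- function(n_clusters = 5, strains_per_cluster = 4,
                                    n_cnvs = 20, n_snps = 2000,
                                    cnv_gain_loss_rate = 0.1,
                                    max_cluster_snp_diff = 150,
                                    cn_states = c(0, 1, 2, 4), seed = NULL) {
  local_seed(seed)
  clusters <- tibble(
    strain = sprintf("S%02d_%02d", rep(seq_len(n_clusters), each = strains_per_cluster),
                     rep(seq_len(strains_per_cluster), n_clusters)),
    cluster = rep(sprintf("C%02d", seq_len(n_clusters)), each = strains_per_cluster)
  )
  n_strains <- nrow(clusters)
  region_ids <- sprintf("cnv%03d", seq_len(n_cnvs))
  # founder states: mostly reference dosage with occasional variants
  cn <- matrix(1, n_strains, n_cnvs, dimnames = list(clusters$strain, region_ids))
  snp <- matrix(0L, n_snps, n_strains,
                dimnames = list(NULL, clusters$strain))
  max_private <- floor(max_cluster_snp_diff / 2)
  for (ci in seq_len(n_clusters)) {
    members <- which(clusters$cluster == sprintf("C%02d", ci))
    founder_cn <- sample(cn_states, n_cnvs, replace = TRUE,
                         prob = c(0.1, 0.7, 0.15, 0.05)[seq_along(cn_states)])
    founder_snp <- rbinom(n_snps, 1, 0.3)
    for (m in members) {
      flips <- runif(n_cnvs) < cnv_gain_loss_rate
      cn_m <- founder_cn
      if (any(flips)) {
        cn_m[flips] <- vapply(founder_cn[flips], function(v) {
          sample(setdiff(cn_states, v), 1)
        }, numeric(1))
      }
      cn[m, ] <- cn_m
      n_priv <- sample.int(max_private + 1, 1) - 1
      g <- founder_snp
      if (n_priv > 0) {
        at <- sample.int(n_snps, min(n_priv, n_snps))
        g[at] <- 1L - g[at]
      }
      snp[, m] <- g
    }
  }
  list(
    cn = bind_cols(tibble(strain = clusters$strain), as_tibble(cn)),
    snps = bind_cols(tibble(chrom = "chr1", pos = seq_len(n_snps) * 100L),
                     as_tibble(snp)),
    clusters = clusters
  )
}

#' Synthesize pairwise crosses with viability driven by genetic distance
#'
#' Builds a pairwise-cross table in which hybrid offspring viability
#' declines independently with SNP distance and with rearrangement
#' distance, while CNV distance is uninformative — the structure under
#' which a partial-correlation analysis should find both controlled
#' effects and dismiss the CNV one. Distances are drawn independently
#' (uniform), viability is `base - b_snp z(snp) - b_rearr z(rearr) +
#' noise`, clamped to \[0, 1\].
#'
#' @param n_crosses Number of crosses (default 58, a typical panel size).
#' @param b_snp,b_rearr Effect sizes on the viability scale per SD of
#'   distance.
#' @param noise_sd Gaussian noise SD on viability.
#' @param base Baseline viability.
#' @param seed Integer seed.
#' @return Tibble with `strain_a`, `strain_b`, `n_snp_diff`,
#'   `n_rearrangement_diff`, `n_cnv_diff`, `viability`.
#' @export
synth_viability_crosses <- function(n_crosses = 58, b_snp = 0.25,
                                    b_rearr = 0.25, noise_sd = 0.08,
                                    base = 0.75, seed = NULL) {
  local_seed(seed)
  snp <- runif(n_crosses)
  rea <- runif(n_crosses)
  cnv <- runif(n_crosses)
  z <- function(v) (v - mean(v)) / sd(v)
  viability <- pmin(1, pmax(0, base - b_snp * z(snp) - b_rearr * z(rea) +
                              rnorm(n_crosses, 0, noise_sd)))
  tibble(
    strain_a = sprintf("P%03d", seq_len(n_crosses)),
    strain_b = sprintf("Q%03d", seq_len(n_crosses)),
    n_snp_diff = round(snp * 60000),
    n_rearrangement_diff = round(rea * 30),
    n_cnv_diff = round(cnv * 40),
    viability = viability
  )
}
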