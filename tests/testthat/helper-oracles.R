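# Independent oracles used across tests. These deliberately take different
# code paths from the package implementation.

# brute-force one-sided rank-sum P by full subset enumeration (tiny n only)
brute_rank_sum <- function(x, y, direction) {
  nx <- length(x)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  idx <- utils::combn(nx + length(y), nx)
  wa <- colSums(matrix(r[idx], nrow = nx))
  if (direction == "greater") mean(wa >= w - 1e-9) else mean(wa <= w + 1e-9)
}

# brute-force evaluation by explicit all-pairs match matrix
brute_evaluate <- function(calls, truth, tol) {
  m <- matrix(FALSE, nrow(calls), nrow(truth))
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(truth))) {
      m[i, j] <- sv_match(calls[i, ], truth[j, ], tol)
    }
  }
  list(
    sensitivity = if (nrow(truth)) mean(apply(m, 2, any)) else NaN,
    fdr = if (nrow(calls)) mean(!apply(m, 1, any)) else NaN
  )
}

# deterministic, evenly spaced truth set (no genome sequence needed)
spaced_truth <- function(n, chrom_lengths, span = 2000, gap = 6000) {
  per <- ceiling(n / length(chrom_lengths))
  rows <- list()
  types <- c("DEL", "DUP", "INV")
  k <- 0
  for (ci in seq_along(chrom_lengths)) {
    chrom <- names(chrom_lengths)[ci]
    s <- 5000
    while (s + span < chrom_lengths[ci] - 5000 && k < n &&
           length(rows) < per * ci) {
      k <- k + 1
      ty <- types[(k %% 3) + 1]
      rows[[k]] <- tibble::tibble(
        type = ty, chrom = chrom, start = as.integer(s),
        end = as.integer(s + span - 1),
        copies = if (ty == "DUP") 2L else NA_integer_
      )
      s <- s + span + gap
    }
  }
  truth_records(dplyr::bind_rows(rows))
}

# tiny deterministic genotype tibble builder for transience/popgen tests
geno_tbl <- function(mat, pos = NULL, chrom = "chr1") {
  tibble::as_tibble(mat) |>
    dplyr::mutate(chrom = chrom, pos = pos %||% (seq_len(nrow(mat)) * 10L),
                  .before = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
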