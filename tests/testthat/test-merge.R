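test_that("within-callset merge collapses 1-kb duplicates to median coordinates", {
  calls <- sv_calls(data.frame(
    type = "DEL", chrom = "chr1", start = c(1000, 1400), end = c(5000, 5300),
    caller = "delly"
  ))
  merged <- merge_within_callset(calls, 1000)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, 1200L)
  expect_equal(merged$end, 5150L)
})

test_that("a single call and cross-type coincidences pass through unchanged", {
  single <- sv_calls(data.frame(type = "INV", chrom = "I", start = 100,
                                end = 900, caller = "c"))
  out <- merge_within_callset(single)
  expect_equal(out$start, single$start)
  expect_equal(out$end, single$end)
  mixed <- sv_calls(data.frame(type = c("DEL", "DUP"), chrom = "I",
                               start = 1000, end = 5000, caller = "c"))
  expect_equal(nrow(merge_within_callset(mixed)), 2)
})

test_that("within-callset merge takes max pe_support and is idempotent", {
  calls <- sv_calls(data.frame(
    type = "DEL", chrom = "I", start = c(1000, 1300, 1600),
    end = c(5000, 5200, 5500), pe_support = c(12L, NA, 30L), caller = "c"
  ))
  once <- merge_within_callset(calls)
  expect_equal(nrow(once), 1)
  expect_equal(once$pe_support, 30L)
  expect_identical(merge_within_callset(once)[, names(once)], once)
  # mixed caller labels rejected
  bad <- dplyr::mutate(calls, caller = c("a", "b", "a"))
  expect_error(merge_within_callset(bad), class = "svkit_precondition_error")
})

test_that("cross-caller clustering follows the pairwise predicate", {
  a <- sv_calls(data.frame(type = "DEL", chrom = "I", start = 1000, end = 5000,
                           caller = "A"))
  b <- sv_calls(data.frame(type = "DEL", chrom = "I", start = 1500, end = 5400,
                           caller = "B"))
  cc <- sv_calls(data.frame(type = "DEL", chrom = "I", start = 9000, end = 9900,
                            caller = "C"))
  cl <- cluster_across_callsets(list(a, b, cc), 1000)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 2)
  expect_equal(cl$cluster_id[cl$caller == "A"], cl$cluster_id[cl$caller == "B"])
  expect_false(cl$cluster_id[cl$caller == "C"] %in%
                 cl$cluster_id[cl$caller == "A"])
})

test_that("single linkage chains transitively beyond the pairwise tolerance", {
  chain <- list(
    sv_calls(data.frame(type = "DEL", chrom = "I", start = 1000, end = 5000,
                        caller = "A")),
    sv_calls(data.frame(type = "DEL", chrom = "I", start = 1900, end = 5900,
                        caller = "B")),
    sv_calls(data.frame(type = "DEL", chrom = "I", start = 2800, end = 6800,
                        caller = "C"))
  )
  cl <- cluster_across_callsets(chain, 1000)
  # A~B and B~C match, A~C does not, yet transitive closure joins all three
  expect_false(sv_match(chain[[1]], chain[[3]], 1000))
  expect_equal(dplyr::n_distinct(cl$cluster_id), 1)
})

test_that("no-overlap callsets produce only singleton clusters", {
  sets <- lapply(1:3, function(i) {
    sv_calls(data.frame(type = "DEL", chrom = "I", start = i * 50000,
                        end = i * 50000 + 2000, caller = LETTERS[i]))
  })
  cl <- cluster_across_callsets(sets, 1000)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 3)
})

test_that("consensus vote keeps >= 2 distinct callers and drops the rest", {
  a <- sv_calls(data.frame(type = "DEL", chrom = "I",
                           start = c(1000, 30000), end = c(5000, 32000),
                           pe_support = c(15L, 20L), caller = "A"))
  a2 <- sv_calls(data.frame(type = "DEL", chrom = "I", start = 30400,
                            end = 32300, pe_support = 9L, caller = "A"))
  b <- sv_calls(data.frame(type = "DEL", chrom = "I", start = 1200,
                           end = 5100, pe_support = 25L, caller = "B"))
  cl <- cluster_across_callsets(list(a, a2, b), 1000)
  cons <- consensus_filter(cl, min_callers = 2)
  # cluster at 1000-5000 has callers {A,B}: kept; cluster at 30000 has two
  # calls but a single caller: dropped
  expect_equal(nrow(cons), 1)
  expect_equal(cons$caller, "consensus")
  expect_equal(cons$pe_support, 25L)
  expect_error(consensus_filter(cl, 0), class = "svkit_parameter_error")
  # raising min_callers never adds calls
  expect_lte(nrow(consensus_filter(cl, 3)), nrow(cons))
})

test_that("consensus coordinates stay within tolerance of a member call", {
  genome <- random_genome(c(I = 2e6, II = 2e6), seed = 50)
  truth <- plan_svs(genome, simulation_spec(n_del = 40, n_dup = 30,
                                            n_inv = 15, n_tra = 15, seed = 51))
  sets <- lapply(c("A", "B", "C"), function(l) {
    mock_caller(truth, mock_caller_profile(0.85, 5, 150, label = l), genome,
                seed = match(l, LETTERS))
  })
  cl <- cluster_across_callsets(sets, 1000)
  cons <- consensus_filter(cl, 2)
  expect_gt(nrow(cons), 0)
  pooled <- dplyr::bind_rows(sets)
  for (i in seq_len(nrow(cons))) {
    members <- pooled[pooled$type == cons$type[i] & pooled$chrom == cons$chrom[i], ]
    expect_true(any(abs(members$start - cons$start[i]) <= 1000 &
                      abs(members$end - cons$end[i]) <= 1000))
  }
  # every kept cluster had >= 2 distinct caller labels
  kept <- dplyr::semi_join(cl, cons,
                           by = c("type", "chrom"))
  expect_true(all(table(unique(kept[, c("cluster_id", "caller")])$cluster_id) >= 1))
})

test_that("paired-end support filter applies the > 10 rule with NA as unknown", {
  calls <- sv_calls(data.frame(
    type = "DEL", chrom = "I", start = c(1, 100, 200) * 1000,
    end = c(2, 101, 201) * 1000, pe_support = c(10L, 11L, NA), caller = "c"
  ))
  expect_warning(kept <- filter_pe_support(calls, 11), "unknown")
  expect_equal(kept$pe_support, 11L)
})

test_that("region filter drops MQ0 breakpoints and double-LTR calls only", {
  ltr <- interval_set(data.frame(chrom = "I", start = c(900, 4900),
                                 end = c(1100, 5100)))
  mq0 <- interval_set(data.frame(chrom = "I", start = 19500, end = 20500))
  calls <- sv_calls(data.frame(
    type = "DEL", chrom = "I",
    start = c(1000, 1000, 30000, 20000),
    end = c(5000, 9000, 35000, 25000),
    caller = "c"
  ))
  kept <- filter_by_regions(calls, ltr = ltr, low_mq = mq0)
  # call 1: both ends in LTRs -> dropped; call 2: only start in LTR -> kept;
  # call 3: clean -> kept; call 4: start in MQ0 -> dropped
  expect_equal(kept$start, c(1000L, 30000L))
  expect_equal(kept$end, c(9000L, 35000L))
  # empty interval sets leave input unchanged
  expect_equal(nrow(filter_by_regions(calls, interval_set(), interval_set())),
               nrow(calls))
})

test_that("pipeline audit records per-stage counts in order", {
  genome <- random_genome(c(I = 1e6, II = 1e6), seed = 60)
  truth <- plan_svs(genome, simulation_spec(n_del = 20, n_dup = 10, seed = 61))
  sets <- lapply(c("A", "B", "C"), function(l) {
    mock_caller(truth, mock_caller_profile(0.8, 10, 150, label = l), genome,
                seed = 100 + match(l, LETTERS))
  })
  out <- consensus_pipeline(sets, min_pe = 11)
  audit <- attr(out, "audit")
  expect_equal(audit$stage,
               c("within-caller merge", "consensus vote", "pe-support filter"))
  expect_true(all(audit$n_out <= audit$n_in))
})
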