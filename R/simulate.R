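#' Specify an SV simulation
#'
#' Describes how many events of each SV type to plant in a reference
#' genome and how large they should be. Event lengths are drawn uniformly
#' within the per-type `[min, max]` range; duplications are tandem with
#' `dup_copies` total copies. Background point variation is controlled by
#' `snp_rate` (substitutions per bp) and `indel_rate` (small indel events
#' per bp); both default to the per-bp densities typical of divergent
#' fission-yeast strains (about 0.1% substitutions, with indels an order
#' of magnitude rarer).
#'
#' @param n_del,n_dup,n_ins,n_inv,n_tra Event counts per type.
#' @param size_range Default length range in bp, used for any type without
#'   its own range.
#' @param size_ranges Optional named list overriding `size_range` per type,
#'   e.g. `list(DEL = c(500, 1000))`. Translocation junction placement
#'   ignores size ranges (a junction is a point).
#' @param dup_copies Total tandem copy count for duplications (>= 2).
#' @param snp_rate,indel_rate Per-bp background mutation rates, each in
#'   \[0, 0.1\].
#' @param min_gap_bp Minimum distance between planned events (and from
#'   chromosome ends), bp.
#' @param seed Integer seed; fixed seed + spec gives byte-identical output.
#' @return A list of class `sv_sim_spec`.
#' @export
simulation_spec <- function(n_del = 0, n_dup = 0, n_ins = 0, n_inv = 0,
                            n_tra = 0, size_range = c(500, 5000),
                            size_ranges = NULL, dup_copies = 2,
                            snp_rate = 0.001, indel_rate = 1e-4,
                            min_gap_bp = 1000, seed = NULL) {
  counts <- c(DEL = n_del, DUP = n_dup, INS = n_ins, INV = n_inv, TRA = n_tra)
  if (any(counts < 0)) abort("simulation_spec(): counts must be >= 0")
  ranges <- stats::setNames(rep(list(as.numeric(size_range)), 5), sv_types())
  for (ty in names(size_ranges %||% list())) {
    assert_sv_type(ty, "size_ranges")
    ranges[[ty]] <- as.numeric(size_ranges[[ty]])
  }
  for (r in ranges) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < 1) {
      abort("simulation_spec(): each size range must be c(min, max), 1 <= min <= max")
    }
  }
  if (dup_copies < 2) abort("simulation_spec(): dup_copies must be >= 2")
  for (r in c(snp_rate, indel_rate)) {
    if (r < 0 || r > 0.1) abort("simulation_spec(): rates must lie in [0, 0.1]")
  }
  structure(
    list(counts = counts, size_ranges = ranges, dup_copies = as.integer(dup_copies),
         snp_rate = snp_rate, indel_rate = indel_rate,
         min_gap_bp = as.integer(min_gap_bp), seed = seed),
    class = "sv_sim_spec"
  )
}

#' Study-like simulation preset
#'
#' Draws a total SV count uniformly in 30–170 (the range used for the
#' simulated benchmark datasets) and splits it across deletions,
#' duplications, inversions and translocations in the proportions of the
#' consensus callset reported for the real population (141:112:26:36).
#'
#' @param seed Integer seed (also drawn into the returned spec).
#' @param n_total Optional fixed total; when `NULL`, drawn from 30–170.
#' @param ... Passed to [simulation_spec()].
#' @return An `sv_sim_spec`.
#' @export
spec_benchmark_mix <- function(seed = NULL, n_total = NULL, ...) {
  local_seed(seed)
  if (is.null(n_total)) n_total <- sample(30:170, 1)
  w <- c(DEL = 141, DUP = 112, INV = 26, TRA = 36)
  n <- floor(n_total * w / sum(w))
  rem <- n_total - sum(n)
  if (rem > 0) {
    add <- order(n_total * w / sum(w) - n, decreasing = TRUE)[seq_len(rem)]
    n[add] <- n[add] + 1
  }
  simulation_spec(n_del = n[["DEL"]], n_dup = n[["DUP"]], n_inv = n[["INV"]],
                  n_tra = n[["TRA"]], seed = seed, ...)
}

#' Plan SV locations on a reference genome
#'
#' Randomly places the events requested by `spec` on the reference:
#' chromosomes are chosen with probability proportional to length, event
#' lengths uniformly within the per-type range. Placement rejects positions
#' that fall within `min_gap_bp` of a chromosome end, of another planned
#' event, or that overlap a run of `N` bases; each event is retried up to
#' 1000 times before a capacity error is raised. Coordinates in the
#' returned truth are *reference* coordinates, 1-based inclusive.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param spec An [simulation_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return Truth tibble ([truth_records()]), sorted by chromosome and start.
#' @export
plan_svs <- function(reference, spec, seed = NULL) {
  if (length(reference) == 0 || all(nchar(reference) == 0)) {
    abort("plan_svs(): empty reference")
  }
  local_seed(seed %||% spec$seed)
  lens <- genome_lengths(reference)
  gap <- spec$min_gap_bp
  has_n <- lapply(reference, function(s) gregexpr("N", s, fixed = TRUE)[[1]])
  n_pos <- lapply(has_n, function(p) if (p[1] == -1) integer(0) else as.integer(p))

  occupied <- tibble(chrom = character(), start = integer(), end = integer())
  clash <- function(chrom, s, e) {
    hit <- occupied$chrom == chrom &
      occupied$start - gap <= e & s <= occupied$end + gap
    any(hit)
  }
  has_n_run <- function(chrom, s, e) {
    p <- n_pos[[chrom]]
    length(p) > 0 && any(p >= s & p <= e)
  }
  place <- function(len, on_chrom = NULL) {
    for (try in seq_len(1000)) {
      chrom <- on_chrom %||% sample(names(lens), 1, prob = lens)
      lo <- gap + 1
      hi <- lens[[chrom]] - gap - len + 1
      if (hi < lo) next
      s <- sample.int(hi - lo + 1, 1) + lo - 1
      e <- s + len - 1
      if (clash(chrom, s, e) || has_n_run(chrom, s, e)) next
      occupied <<- bind_rows(occupied, tibble(chrom = chrom, start = as.integer(s),
                                              end = as.integer(e)))
      return(list(chrom = chrom, start = as.integer(s), end = as.integer(e)))
    }
    abort("plan_svs(): could not place event after 1000 retries (genome too full)",
          class = "svkit_capacity_error")
  }

  rows <- list()
  for (ty in sv_types()) {
    k <- spec$counts[[ty]]
    if (k == 0) next
    rng <- spec$size_ranges[[ty]]
    for (i in seq_len(k)) {
      if (ty == "TRA") {
        if (length(lens) < 2) abort("plan_svs(): TRA needs >= 2 chromosomes")
        pair <- sample(names(lens), 2, prob = lens)
        a <- place(1L, on_chrom = pair[1])
        b <- place(1L, on_chrom = pair[2])
        rows[[length(rows) + 1]] <- tibble(
          type = "TRA", chrom = a$chrom, start = a$start, end = a$start,
          chrom2 = b$chrom, pos2 = b$start, copies = NA_integer_,
          ins_seq = NA_character_
        )
      } else {
        len <- sample(seq.int(rng[1], rng[2]), 1)
        if (ty == "INS") {
          p <- place(1L)
          rows[[length(rows) + 1]] <- tibble(
            type = "INS", chrom = p$chrom, start = p$start, end = p$start,
            chrom2 = NA_character_, pos2 = NA_integer_, copies = NA_integer_,
            ins_seq = random_sequence(len)
          )
        } else {
          p <- place(as.integer(len))
          rows[[length(rows) + 1]] <- tibble(
            type = ty, chrom = p$chrom, start = p$start, end = p$end,
            chrom2 = NA_character_, pos2 = NA_integer_,
            copies = if (ty == "DUP") spec$dup_copies else NA_integer_,
            ins_seq = NA_character_
          )
        }
      }
    }
  }
  out <- if (length(rows)) bind_rows(rows) else empty_truth_tbl()
  out <- arrange(out, .data$chrom, .data$start)
  out$id <- sprintf("%s%05d", out$type, seq_len(nrow(out)))
  truth_records(out)
}

random_sequence <- function(len, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Apply planned SVs to a reference genome
#'
#' Produces the altered genome implied by a truth set: deletions remove
#' `[start, end]`, insertions add `ins_seq` after `start`, tandem
#' duplications insert `copies - 1` extra copies immediately after the
#' source segment, inversions reverse-complement in place, and a
#' translocation reciprocally exchanges the chromosome tails downstream of
#' its two junctions. Non-translocation events are applied in decreasing
#' coordinate order per chromosome; translocation junctions are then
#' shifted by the net length change of events upstream of them, so all
#' truth coordinates remain reference coordinates.
#'
#' @param reference Named character vector of sequences.
#' @param truth Truth tibble with non-overlapping events.
#' @return List of class `simulated_genome` with elements `sequences`,
#'   `truth`, `point_mutations` (empty here; see [add_point_mutations()]).
#' @export
apply_svs <- function(reference, truth) {
  truth <- truth_records(truth)
  check_truth_disjoint(truth)
  seqs <- reference
  non_tra <- filter(truth, .data$type != "TRA")
  for (chrom in unique(non_tra$chrom)) {
    ev <- non_tra |> filter(.data$chrom == !!chrom) |> arrange(dplyr::desc(.data$start))
    s <- seqs[[chrom]]
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      s <- switch(e$type,
        DEL = paste0(substr(s, 1, e$start - 1), substring(s, e$end + 1)),
        INS = paste0(substr(s, 1, e$start), e$ins_seq, substring(s, e$start + 1)),
        DUP = {
          seg <- substr(s, e$start, e$end)
          paste0(substr(s, 1, e$end),
                 strrep(seg, e$copies - 1L),
                 substring(s, e$end + 1))
        },
        INV = paste0(substr(s, 1, e$start - 1),
                     revcomp(substr(s, e$start, e$end)),
                     substring(s, e$end + 1)),
        abort(paste0("apply_svs(): unhandled type ", e$type))
      )
    }
    seqs[[chrom]] <- s
  }
  # translocations: reciprocal tail exchange at shift-corrected junctions
  tra <- filter(truth, .data$type == "TRA")
  shift_at <- function(chrom, pos) {
    ev <- filter(non_tra, .data$chrom == !!chrom, .data$end < pos)
    if (nrow(ev) == 0) return(0L)
    d <- ifelse(ev$type == "DEL", -(ev$end - ev$start + 1L),
         ifelse(ev$type == "INS", nchar(ev$ins_seq),
         ifelse(ev$type == "DUP", (ev$copies - 1L) * (ev$end - ev$start + 1L), 0L)))
    as.integer(sum(d))
  }
  for (i in seq_len(nrow(tra))) {
    e <- tra[i, ]
    ja <- e$start + shift_at(e$chrom, e$start)
    jb <- e$pos2 + shift_at(e$chrom2, e$pos2)
    sa <- seqs[[e$chrom]]; sb <- seqs[[e$chrom2]]
    seqs[[e$chrom]] <- paste0(substr(sa, 1, ja), substring(sb, jb + 1))
    seqs[[e$chrom2]] <- paste0(substr(sb, 1, jb), substring(sa, ja + 1))
  }
  structure(
    list(sequences = seqs, truth = truth,
         point_mutations = empty_mutation_tbl(), spec = NULL),
    class = "simulated_genome"
  )
}

empty_mutation_tbl <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), class = character())
}

check_truth_disjoint <- function(truth) {
  spans <- truth |>
    mutate(s = .data$start, e = pmax(.data$start, .data$end)) |>
    select(all_of(c("chrom", "s", "e")))
  tra2 <- filter(truth, .data$type == "TRA")
  if (nrow(tra2)) {
    spans <- bind_rows(spans, tibble(chrom = tra2$chrom2, s = tra2$pos2,
                                     e = tra2$pos2))
  }
  spans <- arrange(spans, .data$chrom, .data$s)
  bad <- spans |>
    group_by(.data$chrom) |>
    mutate(prev_e = dplyr::lag(.data$e)) |>
    filter(!is.na(.data$prev_e) & .data$s <= .data$prev_e)
  if (nrow(bad) > 0) {
    abort("apply_svs(): truth records overlap on the reference",
          class = "svkit_precondition_error")
  }
  invisible(truth)
}

revcomp <- function(s) {
  chartr("ACGTacgtN", "TGCAtgcaN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Add background SNPs and small indels to a simulated genome
#'
#' Substitution counts per chromosome are Binomial(length, `snp_rate`);
#' substituted bases are never the reference base. Indel event counts are
#' Binomial(length, `indel_rate`) with lengths 1–10 bp, insertion or
#' deletion with equal probability. All changes are recorded in
#' `point_mutations` (positions on the genome as passed in, i.e. after any
#' SVs).
#'
#' @param genome A `simulated_genome` or named character vector.
#' @param snp_rate,indel_rate Per-bp rates in \[0, 0.1\].
#' @param seed Integer seed.
#' @return A `simulated_genome` with mutated `sequences` and filled
#'   `point_mutations`.
#' @export
add_point_mutations <- function(genome, snp_rate = 0.001, indel_rate = 1e-4,
                                seed = NULL) {
  for (r in c(snp_rate, indel_rate)) {
    if (r < 0 || r > 0.1) abort("add_point_mutations(): rates must lie in [0, 0.1]")
  }
  local_seed(seed)
  sim <- if (inherits(genome, "simulated_genome")) genome else
    structure(list(sequences = genome, truth = empty_truth_tbl(),
                   point_mutations = empty_mutation_tbl(), spec = NULL),
              class = "simulated_genome")
  seqs <- sim$sequences
  muts <- list()
  bases <- charToRaw("ACGT")
  for (chrom in names(seqs)) {
    r <- charToRaw(seqs[[chrom]])
    L <- length(r)
    if (L == 0) next
    n_snp <- rbinom(1, L, snp_rate)
    if (n_snp > 0) {
      pos <- sort(sample.int(L, n_snp))
      ref <- rawToChar(r[pos], multiple = TRUE)
      alt <- vapply(ref, function(b) {
        sample(setdiff(c("A", "C", "G", "T"), toupper(b)), 1)
      }, character(1), USE.NAMES = FALSE)
      r[pos] <- charToRaw(paste(alt, collapse = ""))
      muts[[length(muts) + 1]] <- tibble(chrom = chrom, pos = pos, ref = ref,
                                         alt = alt, class = "SNP")
    }
    s <- rawToChar(r)
    n_ind <- rbinom(1, L, indel_rate)
    if (n_ind > 0) {
      pos <- sort(sample.int(nchar(s), n_ind), decreasing = TRUE)
      for (p in pos) {
        ilen <- sample.int(10, 1)
        if (runif(1) < 0.5) {
          ins <- random_sequence(ilen)
          s <- paste0(substr(s, 1, p), ins, substring(s, p + 1))
          muts[[length(muts) + 1]] <- tibble(chrom = chrom, pos = p,
                                             ref = "", alt = ins, class = "INS")
        } else {
          dend <- min(p + ilen - 1, nchar(s))
          muts[[length(muts) + 1]] <- tibble(chrom = chrom, pos = p,
                                             ref = substr(s, p, dend),
                                             alt = "", class = "DEL")
          s <- paste0(substr(s, 1, p - 1), substring(s, dend + 1))
        }
      }
    }
    seqs[[chrom]] <- s
  }
  sim$sequences <- seqs
  sim$point_mutations <- bind_rows(sim$point_mutations,
                                   if (length(muts)) bind_rows(muts) else NULL)
  if (nrow(sim$point_mutations) == 0) sim$point_mutations <- empty_mutation_tbl()
  sim
}

#' Derive the perfect callset from a truth set
#'
#' One call per truth record with identical type and coordinates — the
#' idealised output of an error-free caller, used for round-trip checks of
#' the evaluation machinery.
#'
#' @param truth Truth tibble.
#' @param pe_support Paired-end support assigned to every call.
#' @param caller Caller label.
#' @return Tibble of SV calls.
#' @export
perfect_callset <- function(truth, pe_support = 30L, caller = "truth") {
  truth <- truth_records(truth)
  if (nrow(truth) == 0) return(empty_sv_tbl())
  sv_calls(tibble(
    id = truth$id, type = truth$type, chrom = truth$chrom,
    start = truth$start, end = truth$end, chrom2 = truth$chrom2,
    pos2 = truth$pos2,
    length = ifelse(truth$type == "INS", nchar(truth$ins_seq),
             ifelse(truth$type == "TRA", NA_integer_,
                    truth$end - truth$start + 1L)),
    pe_support = as.integer(pe_support), caller = caller
  ))
}

#' Simulate a full SV genome in one step
#'
#' Convenience wrapper: [plan_svs()], [apply_svs()], then
#' [add_point_mutations()] using the rates in `spec`.
#'
#' @inheritParams plan_svs
#' @return A `simulated_genome` with `spec` attached.
#' @export
simulate_sv_genome <- function(reference, spec, seed = NULL) {
  seed <- seed %||% spec$seed
  local_seed(seed)
  truth <- plan_svs(reference, spec, seed = NULL)
  sim <- apply_svs(reference, truth)
  sim <- add_point_mutations(sim, spec$snp_rate, spec$indel_rate, seed = NULL)
  sim$spec <- spec
  sim
}

#' @export
print.simulated_genome <- function(x, ...) {
  cat("Simulated genome:", length(x$sequences), "chromosome(s),",
      format(sum(nchar(x$sequences)), big.mark = ","), "bp\n")
  cat("  truth events: ", nrow(x$truth), " (",
      paste(names(table(x$truth$type)), table(x$truth$type),
            sep = ":", collapse = ", "), ")\n", sep = "")
  cat("  point mutations:", nrow(x$point_mutations), "\n")
  invisible(x)
}
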