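#' Read structural variant calls from VCF
#'
#' Normalizes caller-specific SV encodings to one tibble of calls (see
#' [sv_calls()]). The SV type is taken from the `SVTYPE` INFO key, or from
#' a symbolic ALT allele (`<DEL>`, `<DUP>`, ...), or recognised as a
#' breakend (`BND`) from the bracketed ALT syntax. `END` is taken from
#' INFO; when absent it is computed from `SVLEN` (end = pos + |SVLEN| - 1).
#' Translocations are accepted in two dialects: a single record with
#' `SVTYPE=TRA` plus `CHR2`/`POS2` (or `CHR2`+`END`), and breakend pairs —
#' a reciprocal BND mate pair (linked by `MATEID` or by mirrored
#' coordinates) collapses to one `TRA` call. Records whose type cannot be
#' determined are skipped and counted in a message, never silently dropped.
#'
#' @param path VCF file (4.x; plain text or bgzipped).
#' @param caller_label Caller label stored in the `caller` column.
#' @return Tibble of SV calls. Attribute `skipped` holds the number of
#'   records dropped for unparseable type.
#' @export
read_sv_vcf <- function(path, caller_label = "unknown") {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("Failed to parse VCF ", path, ": ",
                                     conditionMessage(e)),
                              class = "svkit_format_error")
  )
  fix <- vcf@fix
  if (nrow(fix) == 0) {
    out <- empty_sv_tbl()
    attr(out, "skipped") <- 0L
    return(out)
  }
  contig_len <- parse_contig_lengths(vcf@meta)
  info <- fix[, "INFO"]
  getinfo <- function(key) {
    m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    m
  }
  alt <- fix[, "ALT"]
  svtype <- getinfo("SVTYPE")
  sym <- stringr::str_match(alt, "^<([A-Z:]+)>$")[, 2]
  sym <- sub(":.*$", "", sym)
  type <- ifelse(!is.na(svtype), svtype, sym)
  is_bnd_alt <- stringr::str_detect(alt, "\\[|\\]")
  type[is.na(type) & is_bnd_alt] <- "BND"
  type[!is.na(type) & type %in% c("BND", "CTX", "ITX")] <- "BND"

  pos <- as.integer(fix[, "POS"])
  end <- suppressWarnings(as.integer(getinfo("END")))
  svlen <- suppressWarnings(as.integer(getinfo("SVLEN")))
  chr2 <- getinfo("CHR2")
  pos2 <- suppressWarnings(as.integer(getinfo("POS2")))
  pe <- suppressWarnings(as.integer(getinfo("PE")))
  mateid <- getinfo("MATEID")
  id <- fix[, "ID"]
  chrom <- fix[, "CHROM"]

  keep <- !is.na(type) & (type %in% sv_types() | type == "BND")
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    inform(paste0("read_sv_vcf(): skipped ", n_skip,
                  " record(s) with unparseable SV type"))
  }

  rows <- list()
  consumed <- rep(FALSE, nrow(fix))
  for (i in which(keep)) {
    if (consumed[i]) next
    ty <- type[i]
    if (ty == "BND") {
      mate <- parse_bnd_alt(alt[i])
      j <- NA_integer_
      if (!is.na(mateid[i])) {
        j <- which(id == mateid[i] & !consumed)
        j <- if (length(j)) j[1] else NA_integer_
      }
      if (is.na(j) && !is.na(mate$chrom)) {
        cand <- which(type == "BND" & chrom == mate$chrom &
                        abs(pos - mate$pos) <= 1 & !consumed)
        cand <- setdiff(cand, i)
        j <- if (length(cand)) cand[1] else NA_integer_
      }
      if (!is.na(j)) consumed[j] <- TRUE
      consumed[i] <- TRUE
      p2 <- if (!is.na(mate$chrom)) mate$pos else pos2[i]
      c2 <- if (!is.na(mate$chrom)) mate$chrom else chr2[i]
      if (is.na(c2)) next   # unresolvable breakend; counted below
      rows[[length(rows) + 1]] <- tibble(
        id = id[i], type = "TRA", chrom = chrom[i], start = pos[i],
        end = pos[i], chrom2 = c2, pos2 = as.integer(p2),
        length = NA_integer_, pe_support = pe[i]
      )
    } else if (ty == "TRA") {
      consumed[i] <- TRUE
      c2 <- chr2[i]
      p2 <- if (!is.na(pos2[i])) pos2[i] else end[i]
      if (is.na(c2) || is.na(p2)) next
      rows[[length(rows) + 1]] <- tibble(
        id = id[i], type = "TRA", chrom = chrom[i], start = pos[i],
        end = pos[i], chrom2 = c2, pos2 = as.integer(p2),
        length = NA_integer_, pe_support = pe[i]
      )
    } else {
      consumed[i] <- TRUE
      e <- end[i]
      if (is.na(e) && !is.na(svlen[i])) e <- pos[i] + abs(svlen[i]) - 1L
      if (ty == "INS") {
        e <- if (is.na(e)) pos[i] else pos[i]
        len <- if (!is.na(svlen[i])) abs(svlen[i]) else NA_integer_
      } else {
        if (is.na(e)) next
        len <- e - pos[i] + 1L
      }
      if (!is.na(contig_len[chrom[i]]) && e > contig_len[chrom[i]]) {
        abort(sprintf(
          "read_sv_vcf(): record %s at %s:%d-%d exceeds contig length %d",
          id[i], chrom[i], pos[i], e, contig_len[chrom[i]]
        ), class = "svkit_format_error")
      }
      rows[[length(rows) + 1]] <- tibble(
        id = id[i], type = ty, chrom = chrom[i], start = pos[i],
        end = as.integer(e), chrom2 = NA_character_, pos2 = NA_integer_,
        length = as.integer(len), pe_support = pe[i]
      )
    }
  }
  out <- if (length(rows)) bind_rows(rows) else empty_sv_tbl()
  out$caller <- caller_label
  out <- sv_calls(out, caller = caller_label)
  attr(out, "skipped") <- n_skip
  out
}

parse_contig_lengths <- function(meta) {
  m <- stringr::str_match(meta, "^##contig=<ID=([^,>]+),length=(\\d+)")
  ok <- !is.na(m[, 2])
  stats::setNames(as.integer(m[ok, 3]), m[ok, 2])
}

parse_bnd_alt <- function(alt) {
  m <- stringr::str_match(alt, "[\\[\\]]([^\\[\\]:]+):(\\d+)[\\[\\]]")
  list(chrom = m[, 2], pos = as.integer(m[, 3]))
}

#' Write structural variant calls to VCF
#'
#' Emits VCF 4.2 with symbolic ALT alleles and `SVTYPE`/`END`/`SVLEN`/`PE`
#' INFO keys. Translocations are written by default as one record with
#' `SVTYPE=TRA;CHR2=...;POS2=...` (DELLY dialect); `tra_style = "bnd"`
#' writes a reciprocal breakend mate pair instead. Either form re-reads as
#' a single `TRA` call.
#'
#' @param calls Tibble of SV calls ([sv_calls()]).
#' @param path Output file.
#' @param contigs Optional named vector of contig lengths for the header;
#'   when `NULL`, lengths are taken as the maximum coordinate seen per
#'   chromosome.
#' @param tra_style `"chr2"` (single record, default) or `"bnd"`.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path, contigs = NULL,
                         tra_style = c("chr2", "bnd")) {
  tra_style <- match.arg(tra_style)
  calls <- sv_calls(calls)
  if (is.null(contigs)) {
    pos_tbl <- tibble(
      chrom = c(calls$chrom, calls$chrom2[!is.na(calls$chrom2)]),
      pos = c(pmax(calls$start, calls$end), calls$pos2[!is.na(calls$chrom2)])
    )
    contigs <- if (nrow(pos_tbl)) {
      tapply(pos_tbl$pos, pos_tbl$chrom, max)
    } else {
      numeric(0)
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svkit",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Partner chromosome\">",
    "##INFO=<ID=POS2,Number=1,Type=Integer,Description=\"Partner position\">",
    "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"Paired-end support\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Breakend mate\">",
    "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"Source caller\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  recs <- character(0)
  for (i in seq_len(nrow(calls))) {
    x <- calls[i, ]
    pe <- if (is.na(x$pe_support)) "" else paste0(";PE=", x$pe_support)
    cl <- paste0(";CALLER=", x$caller)
    if (x$type == "TRA") {
      if (tra_style == "chr2") {
        info <- paste0("SVTYPE=TRA;CHR2=", x$chrom2, ";POS2=", x$pos2, pe, cl)
        recs <- c(recs, paste(x$chrom, x$start, x$id, "N", "<TRA>", ".",
                              "PASS", info, sep = "\t"))
      } else {
        id1 <- paste0(x$id, "_1"); id2 <- paste0(x$id, "_2")
        a1 <- sprintf("N[%s:%d[", x$chrom2, x$pos2)
        a2 <- sprintf("N[%s:%d[", x$chrom, x$start)
        recs <- c(recs,
          paste(x$chrom, x$start, id1, "N", a1, ".", "PASS",
                paste0("SVTYPE=BND;MATEID=", id2, pe, cl), sep = "\t"),
          paste(x$chrom2, x$pos2, id2, "N", a2, ".", "PASS",
                paste0("SVTYPE=BND;MATEID=", id1, pe, cl), sep = "\t"))
      }
    } else {
      len <- if (!is.na(x$length)) x$length else x$end - x$start + 1L
      svlen <- switch(x$type, DEL = -len, len)
      info <- paste0("SVTYPE=", x$type, ";END=", x$end, ";SVLEN=", svlen,
                     pe, cl)
      recs <- c(recs, paste(x$chrom, x$start, x$id, "N",
                            paste0("<", x$type, ">"), ".", "PASS", info,
                            sep = "\t"))
    }
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
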