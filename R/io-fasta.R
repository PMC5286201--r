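#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences; names are the
#'   first whitespace-separated token of each FASTA header.
#' @export
read_genome <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("read_genome() requires the Biostrings package")
  }
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output file.
#' @param width Line width (default 70).
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    L <- nchar(s)
    if (L > 0) {
      starts <- seq(1, L, by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, L)), con)
    }
  }
  invisible(path)
}

genome_lengths <- function(genome) {
  if (is.numeric(genome)) {
    stats::setNames(as.numeric(genome), names(genome))
  } else {
    stats::setNames(as.numeric(nchar(genome)), names(genome))
  }
}
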