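#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and returned as a named character vector
#' keyed by chromosome name (the FASTA header up to the first
#' whitespace). Only A/C/G/T/N are accepted.
#'
#' @param path path to a FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA header: ", nm[duplicated(nm)][1])
  }
  if (any(nm == "")) stop("empty FASTA header")
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for entry: ", nm[nchar(seqs) == 0][1])
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("invalid character in sequence '", nm[i], "' at position ",
         bad[i])
  }
  names(seqs) <- nm
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Write and read tab-separated report tables
#'
#' All tabular pipeline outputs are TSV with a header row; round-trips
#' are lossless for the column types the pipeline uses.
#'
#' @param table a data.frame.
#' @param path file path.
#' @export
write_tsv_report <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv_report
#' @export
read_tsv_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
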