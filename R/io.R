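# Plain-text I/O: FASTQ (Sanger Phred+33), FASTA, TSV.

#' Write reads as Sanger FASTQ
#'
#' @param reads data.frame with `id`, `bases` and a `quals` list-column of
#'   integer Phred scores.
#' @param path Output path.
#' @export
write_reads_fastq <- function(reads, path) {
  qstr <- vapply(reads$quals, function(q) {
    rawToChar(as.raw(as.integer(q) + 33L))
  }, "")
  lines <- as.vector(rbind(paste0("@", reads$id), reads$bases, "+", qstr))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Sanger FASTQ file
#'
#' @param path FASTQ path.
#' @return data.frame: `id`, `bases`, `quals` (list of integer Phred
#'   scores).
#' @export
read_reads_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ", call. = FALSE)
  idx <- seq(1L, length(lines), by = 4L)
  data.frame(
    id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
    bases = toupper(lines[idx + 1L]),
    quals = I(lapply(lines[idx + 3L], function(q) {
      as.integer(charToRaw(q)) - 33L
    })),
    stringsAsFactors = FALSE)
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  writeXStringSet(DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  ss <- readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a data.frame as TSV
#'
#' @param x data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  x <- x[, !vapply(x, is.list, TRUE), drop = FALSE]
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
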