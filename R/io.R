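#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (Sanger Phred+33 qualities).
#' @return A data frame with columns `read_id`, `sequence`, `quality`
#'   (quality as a Phred+33 string of the same length as the sequence).
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropped metadata columns when re-packing the
  # qualities; the values themselves are retained
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(
    read_id = names(x),
    sequence = as.character(x),
    quality = as.character(Biostrings::quality(x)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a read table to FASTQ
#'
#' @param reads data frame with `read_id`, `sequence`, `quality` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read / write FASTA sequence tables
#'
#' `read_fasta()` returns a data frame with `id` and `sequence`;
#' `write_fasta()` is its inverse.
#'
#' @param path FASTA file.
#' @return `read_fasta()`: a data frame; `write_fasta()`: `path`, invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(id = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences, or a data frame with
#'   `id` and `sequence` columns.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) {
    s <- seqs$sequence
    names(s) <- seqs$id
    seqs <- s
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write the barcode mapping file
#'
#' Tab-separated with a single header line `#sample_id<TAB>barcode`.
#'
#' @param path mapping file.
#' @return `read_mapping()`: a data frame with `sample_id`, `barcode`.
#' @export
read_mapping <- function(path) {
  m <- read.delim(path, comment.char = "", stringsAsFactors = FALSE)
  names(m) <- sub("^X\\.", "", names(m))          # "#sample_id" -> "sample_id"
  names(m)[1] <- sub("^#", "", names(m)[1])
  validate_mapping(m[, c("sample_id", "barcode")])
}

#' @rdname read_mapping
#' @param mapping data frame with `sample_id` and `barcode`.
#' @export
write_mapping <- function(mapping, path) {
  validate_mapping(mapping)
  writeLines(c("#sample_id\tbarcode",
               paste(mapping$sample_id, mapping$barcode, sep = "\t")), path)
  invisible(path)
}

# Internal TSV helpers: all pipeline tables are TSV with a '#'-prefixed header.
write_tsv <- function(df, path) {
  header <- paste0("#", paste(names(df), collapse = "\t"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(df)) {
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

read_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
  df <- read.delim(path, header = FALSE, skip = 1L, stringsAsFactors = FALSE,
                   col.names = cols)
  df
}
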