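#' Primer and probe set for the 18S V1-V3 amplicon
#'
#' The universal eukaryotic forward primer 1A and reverse primer 564R bracket
#' the hypervariable V1-V3 region of the 18S rRNA gene; the two internal
#' oligonucleotide probes Euk381 and Euk422 lie between them.  A genuine 18S
#' amplicon read therefore starts with the complete forward primer and carries
#' at least one of the probes downstream, which is the basis of the
#' false-amplicon screen in [probe_screen()].
#'
#' @param forward_primer,reverse_primer,probes optional overrides; DNA strings
#'   over `A`, `C`, `G`, `T` (probes as a named character vector).
#' @return An object of class `probe_set`.
#' @examples
#' probe_set()
#' @export
probe_set <- function(forward_primer = "AACCTGGTTGATCCTGCCAG",
                      reverse_primer = "GGCACCAGACTTGCCCTC",
                      probes = c(Euk381 = "TCCGGAGAGGGAGCC",
                                 Euk422 = "GGCAGCAGGCACGAA")) {
  chk <- function(x) all(grepl("^[ACGT]+$", x))
  if (!chk(forward_primer) || !chk(reverse_primer) || !chk(probes))
    stop("primer and probe sequences must be uppercase ACGT")
  structure(list(forward_primer = forward_primer,
                 reverse_primer = reverse_primer,
                 probes = probes),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat("Probe set for 18S amplicon screening\n")
  cat("  forward primer:", x$forward_primer, "\n")
  cat("  reverse primer:", x$reverse_primer, "\n")
  for (nm in names(x$probes)) cat(sprintf("  probe %s: %s\n", nm, x$probes[nm]))
  invisible(x)
}

#' Default barcode-to-sample mapping of the seven-site study design
#'
#' Seven habitats in and around a deep-sea brine pool: a microbial mat (Mat),
#' normal bottom water (NDW), the brine-seawater interface (DBI), two bottom
#' sediments (DS3, DS6) and two brine-pool sediments (BS8, BS9), each tagged
#' with an 8-nt barcode.
#'
#' @return A data frame with columns `sample_id` and `barcode`.
#' @examples
#' default_mapping()
#' @export
default_mapping <- function() {
  data.frame(
    sample_id = c("Mat", "NDW", "DBI", "DS3", "DS6", "BS8", "BS9"),
    barcode = c("CGGATTGC", "ATGCAGTC", "ATATTCGC", "TTATCCGC",
                "TATCGTCC", "ACCACAAC", "TCTGCGTT"),
    stringsAsFactors = FALSE
  )
}

validate_mapping <- function(mapping) {
  if (!is.data.frame(mapping) ||
      !all(c("sample_id", "barcode") %in% names(mapping)))
    stop("mapping must be a data frame with columns sample_id, barcode")
  if (anyDuplicated(mapping$barcode))
    stop("duplicate barcodes in mapping")
  if (anyDuplicated(mapping$sample_id))
    stop("duplicate sample ids in mapping")
  if (length(unique(nchar(mapping$barcode))) > 1L)
    stop("all barcodes must have the same length")
  if (!all(grepl("^[ACGT]+$", mapping$barcode)))
    stop("barcodes must be uppercase ACGT")
  invisible(mapping)
}
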