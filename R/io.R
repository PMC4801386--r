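#' Read a CDS reference from FASTA
#'
#' @param path Path to a (possibly multi-record) nucleotide FASTA file.
#' @return Tibble with `cds_id`, `sequence`, `length`. Identifiers are the
#'   first whitespace-delimited token of each header.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  tibble::tibble(cds_id = ids, sequence = unname(as.character(x)),
                 length = Biostrings::width(x))
}

#' Write a CDS reference to FASTA
#'
#' @param cds Tibble with `cds_id` and `sequence` columns.
#' @param path Output path.
#' @export
write_cds_fasta <- function(cds, path) {
  x <- Biostrings::DNAStringSet(cds$sequence)
  names(x) <- cds$cds_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read one FASTQ library
#'
#' @param path Path to an uncompressed or gzipped FASTQ file (Phred+33).
#' @param library_label One of `FSG`, `MSG`, `FWB`, `MWB` (or any label for
#'   standalone use).
#' @return Tibble with `read_id`, `sequence`, `quality`, `library_label`.
#' @export
read_fastq_library <- function(path, library_label = NA_character_) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble::tibble(read_id = sub("\\s.*$", "", names(x)),
                 sequence = unname(as.character(x)),
                 quality = unname(as.character(S4Vectors::mcols(x)$qualities)),
                 library_label = library_label)
}

#' Write one read library to FASTQ (Phred+33)
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @export
write_fastq_library <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::PhredQuality(reads$quality))
  names(x) <- reads$read_id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

# plain TSV with header, no quoting: the exchange format of every pipeline
# stage
write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_file <- function(path) {
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE, check.names = FALSE))
}
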