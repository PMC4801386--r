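# codon -> amino acid lookup built from the standard genetic code; codons
# containing anything outside A/C/G/T (e.g. N) translate to 'X' and never
# terminate an ORF
translate_codons <- function(seq_chars, offset, n_codons) {
  gc <- Biostrings::GENETIC_CODE
  if (n_codons == 0) return(character(0))
  starts <- offset + 3 * (seq_len(n_codons) - 1) + 1
  codons <- paste0(seq_chars[starts], seq_chars[starts + 1], seq_chars[starts + 2])
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Longest open reading frame over six frames
#'
#' Scans all six reading frames of a contig. An ORF is a maximal stop-free
#' codon run, optionally bounded by a stop codon; a methionine start is NOT
#' required (Met presence is reported as a flag, not used as a filter).
#' Returns the longest ORF by protein length; ties are broken by frame
#' order (+1, +2, +3, -1, -2, -3), then by leftmost start within the frame.
#'
#' @param contig A nucleotide string (or `DNAString`), length >= 3.
#' @return One-row tibble: `frame` (+1..+3 forward, -1..-3 reverse),
#'   `start`, `end` (0-based half-open offsets on the contig's forward
#'   strand; the region includes the terminal stop codon when present, so
#'   `end - start` is divisible by 3), `protein` (amino-acid string, stop
#'   excluded), `starts_with_met`, `ends_with_stop`.
#' @export
longest_orf <- function(contig) {
  s <- toupper(as.character(contig))
  L <- nchar(s)
  if (L < 3) stop("contig must be at least 3 nt long")
  fwd <- strsplit(s, "", fixed = TRUE)[[1]]
  rev <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s))), "", fixed = TRUE)[[1]]

  best <- NULL
  frames <- list(c(1, 0), c(2, 0), c(3, 0), c(-1, 1), c(-2, 1), c(-3, 1))
  for (fr in frames) {
    f <- fr[1]
    chars <- if (fr[2] == 0) fwd else rev
    offset <- abs(f) - 1
    n_codons <- (L - offset) %/% 3
    if (n_codons == 0) next
    aa <- translate_codons(chars, offset, n_codons)
    is_stop <- aa == "*"
    # maximal stop-free runs (may be empty if every codon is a stop)
    r <- rle(is_stop)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in seq_along(r$values)) {
      if (r$values[i]) next
      run_start <- starts[i]; run_end <- ends[i]
      plen <- run_end - run_start + 1
      has_stop <- run_end < n_codons  # followed by a stop codon in-frame
      if (!is.null(best) && plen < best$plen) next
      # strand-local nt region, including the terminal stop codon if present
      cs <- offset + 3 * (run_start - 1)
      ce <- offset + 3 * (run_end + as.integer(has_stop))
      if (fr[2] == 1) { tmp <- cs; cs <- L - ce; ce <- L - tmp }
      cand <- list(frame = f, start = cs, end = ce,
                   protein = paste(aa[run_start:run_end], collapse = ""),
                   starts_with_met = aa[run_start] == "M",
                   ends_with_stop = has_stop, plen = plen)
      if (is.null(best) || plen > best$plen) best <- cand
      # ties: frame order is the loop order; within a frame the first
      # (leftmost in scanning orientation) run wins, so never replace on ties
    }
  }
  if (is.null(best)) stop("no open reading frame found")  # every codon in every frame is a stop
  tibble::tibble(frame = best$frame, start = as.integer(best$start),
                 end = as.integer(best$end), protein = best$protein,
                 starts_with_met = best$starts_with_met,
                 ends_with_stop = best$ends_with_stop)
}

#' ORF table for a contig set
#'
#' Applies [longest_orf()] to every contig.
#'
#' @param contigs Named character vector, tibble with `cds_id`/`sequence`,
#'   or `DNAStringSet`.
#' @return Tibble: `contig_id`, `frame`, `start`, `end`, `protein_len`,
#'   `starts_with_met`, `ends_with_stop`, `protein`.
#' @export
orf_table <- function(contigs) {
  if (is.data.frame(contigs)) {
    ids <- contigs$cds_id
    seqs <- contigs$sequence
  } else {
    seqs <- as.character(contigs)
    ids <- names(seqs)
    if (is.null(ids)) ids <- sprintf("contig%05d", seq_along(seqs))
  }
  rows <- lapply(seq_along(seqs), function(i) {
    o <- longest_orf(seqs[i])
    tibble::tibble(contig_id = ids[i], frame = o$frame, start = o$start,
                   end = o$end, protein_len = nchar(o$protein),
                   starts_with_met = o$starts_with_met,
                   ends_with_stop = o$ends_with_stop, protein = o$protein)
  })
  dplyr::bind_rows(rows)
}

#' Was a protein prediction extended by at least 25 percent?
#'
#' @param new_protein_len Length (aa) of the reassembled prediction.
#' @param ref_protein_len Length (aa) of the reference annotation.
#' @return `TRUE` when `new_protein_len >= 1.25 * ref_protein_len`
#'   (inclusive). Vectorized.
#' @export
assess_extension <- function(new_protein_len, ref_protein_len) {
  if (any(new_protein_len <= 0) || any(ref_protein_len <= 0))
    stop("protein lengths must be > 0")
  new_protein_len >= 1.25 * ref_protein_len
}

#' Validate extended predictions against an outgroup proteome
#'
#' Applies the cross-proteome validation thresholds to externally supplied
#' alignment summaries. `"drosophila"` mode: e-value below 1e-15 and query
#' length within 10 percent of the subject length. `"culex"` mode: query
#' coverage above 90 percent of the subject with identity below 95 percent.
#'
#' @param summary Tibble/data.frame with columns `evalue`, `identity_pct`,
#'   `query_coverage_pct`, `query_len`, `subject_len` (only the columns the
#'   chosen mode uses are required).
#' @param mode `"drosophila"` or `"culex"`.
#' @return Logical vector, one element per summary row.
#' @export
validate_against_outgroup <- function(summary, mode = c("drosophila", "culex")) {
  mode <- match.arg(mode)
  if (mode == "drosophila") {
    need <- c("evalue", "query_len", "subject_len")
    if (!all(need %in% names(summary)))
      stop("drosophila mode needs columns evalue, query_len, subject_len")
    if (any(summary$query_len <= 0) || any(summary$subject_len <= 0))
      stop("lengths must be > 0")
    summary$evalue < 1e-15 &
      abs(summary$query_len - summary$subject_len) <= 0.10 * summary$subject_len
  } else {
    need <- c("query_coverage_pct", "identity_pct")
    if (!all(need %in% names(summary)))
      stop("culex mode needs columns query_coverage_pct, identity_pct")
    summary$query_coverage_pct > 90 & summary$identity_pct < 95
  }
}

#' Read a 12-column tabular alignment summary
#'
#' Standard tabular alignment output (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bit score), with optional 13th/14th columns for
#' query and subject length. When lengths are present, query coverage is
#' derived as `100 * |qend - qstart + 1| / subject_len`.
#'
#' @param path Path to the tab-separated file (no header).
#' @return Tibble with named columns (`query_id`, `subject_id`,
#'   `identity_pct`, ..., `evalue`, `bitscore`, and when present
#'   `query_len`, `subject_len`, `query_coverage_pct`).
#' @export
read_alignment_summary <- function(path) {
  x <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  base_cols <- c("query_id", "subject_id", "identity_pct", "aln_len",
                 "mismatches", "gap_opens", "qstart", "qend", "sstart",
                 "send", "evalue", "bitscore")
  if (ncol(x) < 12) stop("expected at least 12 tab-separated columns")
  names(x)[1:12] <- base_cols
  if (ncol(x) >= 14) {
    names(x)[13:14] <- c("query_len", "subject_len")
    x$query_coverage_pct <- 100 * abs(x$qend - x$qstart + 1) / x$subject_len
  }
  tibble::as_tibble(x)
}
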