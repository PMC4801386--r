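#' Alignment parameters for read-to-CDS assignment
#'
#' The mapping rule is blastn-like: candidate CDS are found through shared
#' exact `word_size`-mers on either strand, alignments must place the whole
#' read inside the CDS with at most one gap of length up to `max_gap_len`,
#' and are discarded below `min_identity` percent identity (gap columns
#' count against identity). Among surviving assignments of a read only
#' those tied at the maximal score are retained, at most `max_hits` of
#' them (ties beyond that resolved by ascending `cds_id`). The default
#' scoring is megablast-like.
#'
#' @param word_size Exact-match seed length (nt).
#' @param min_identity Minimum percent identity of a retained alignment.
#' @param max_gap_len Maximum length of the single allowed gap.
#' @param max_hits Maximum equally-best assignments kept per read.
#' @param match,mismatch Per-base match reward and mismatch penalty.
#' @param gap_open,gap_extend Gap penalties; a length-`g` gap costs
#'   `gap_open + g * gap_extend`.
#' @return A list of class `map_params`.
#' @export
map_params <- function(word_size = 25L, min_identity = 95, max_gap_len = 3L,
                       max_hits = 5L, match = 2L, mismatch = -3L,
                       gap_open = 5L, gap_extend = 2L) {
  stopifnot(word_size >= 1, min_identity > 0, min_identity <= 100,
            max_gap_len >= 0, max_hits >= 1)
  structure(list(word_size = as.integer(word_size),
                 min_identity = min_identity,
                 max_gap_len = as.integer(max_gap_len),
                 max_hits = as.integer(max_hits),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "map_params")
}

#' Trim low-quality 3' ends and drop short reads
#'
#' Removes the maximal run of trailing bases whose Phred quality is below
#' `threshold`, then drops reads shorter than `min_length` (by default the
#' seed word size, below which a read cannot be mapped). The alternative
#' policy of discarding any read containing a base below threshold is
#' available via `mode = "discard"`.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` (Phred+33
#'   strings), e.g. from [read_fastq_library()] or [synthesize_reads()].
#' @param threshold Phred quality below which trailing bases are trimmed.
#' @param min_length Minimum retained read length after trimming.
#' @param mode `"trim"` (default, 3' base trimming) or `"discard"`
#'   (drop whole reads containing any base below threshold).
#' @return The trimmed tibble, with attributes `n_input`, `n_dropped`.
#' @export
trim_reads <- function(reads, threshold = 13L, min_length = 25L,
                       mode = c("trim", "discard")) {
  mode <- match.arg(mode)
  n_in <- nrow(reads)
  if (n_in == 0) {
    out <- reads
  } else if (mode == "discard") {
    hi <- min(33 + threshold - 1, 126)
    bad <- grepl(sprintf("[\\x21-\\x%02X]", hi), reads$quality, perl = TRUE)
    keep <- !bad & nchar(reads$sequence) >= min_length
    out <- reads[keep, ]
  } else {
    hi <- min(33 + threshold - 1, 126)
    newq <- sub(sprintf("[\\x21-\\x%02X]+$", hi), "", reads$quality, perl = TRUE)
    newlen <- nchar(newq)
    out <- reads
    out$quality <- newq
    out$sequence <- substr(out$sequence, 1L, newlen)
    out <- out[newlen >= min_length, ]
  }
  attr(out, "n_input") <- n_in
  attr(out, "n_dropped") <- n_in - nrow(out)
  out
}

#' Assign reads to CDS by seeded alignment
#'
#' Maps each read (both strands) against the CDS reference under the rule
#' described in [map_params()], implemented as a compiled seed-and-extend
#' search over a `word_size`-mer index of the reference.
#'
#' @param reads Tibble with `read_id`, `sequence` and optionally
#'   `library_label` (carried through to the assignments).
#' @param reference Tibble with `cds_id`, `sequence` (e.g. from
#'   [read_cds_fasta()] or [generate_cds_set()]).
#' @param params A [map_params()] object.
#' @return Assignment tibble: `read_id`, `cds_id`, `score`, `identity`,
#'   `gaps` (0 or 1), `gap_len`, `strand`, plus `library_label` if present
#'   in `reads`. Per read, all rows share the maximal score and there are at
#'   most `max_hits` of them; unmapped reads contribute no rows.
#' @export
map_reads <- function(reads, reference, params = map_params()) {
  empty <- tibble::tibble(read_id = character(), cds_id = character(),
                          score = numeric(), identity = numeric(),
                          gaps = integer(), gap_len = integer(),
                          strand = character())
  has_lib <- "library_label" %in% names(reads)
  if (has_lib) empty$library_label <- character()
  if (nrow(reads) == 0 || nrow(reference) == 0) return(empty)
  res <- .map_reads_cpp(reads$sequence, reference$sequence, reference$cds_id,
                        word_size = params$word_size,
                        min_identity = params$min_identity,
                        max_gap_len = params$max_gap_len,
                        max_hits = params$max_hits,
                        match = params$match, mismatch = params$mismatch,
                        gap_open = params$gap_open,
                        gap_extend = params$gap_extend)
  out <- tibble::tibble(
    read_id = reads$read_id[res$read_index],
    cds_id = reference$cds_id[res$cds_index],
    score = res$score,
    identity = res$identity,
    gaps = as.integer(res$gap_len > 0),
    gap_len = res$gap_len,
    strand = res$strand)
  if (has_lib) out$library_label <- reads$library_label[res$read_index]
  out
}

#' Build the per-CDS, per-library count matrix
#'
#' Each retained assignment increments its `(cds, library)` cell. Under the
#' default whole-count policy a read tied between k CDS adds 1 to each of
#' the k cells (and k to the library total); the fractional policy adds
#' 1/k instead.
#'
#' @param assignments Assignment tibble from [map_reads()], with a
#'   `library_label` column.
#' @param reference Tibble with `cds_id` (defines row order; CDS without
#'   assignments get zero counts).
#' @param policy `"whole"` (default) or `"fractional"`.
#' @return A list of class `count_matrix`: `counts` (tibble `cds_id`,
#'   `r_FSG` .. `r_MWB`) and `totals` (named numeric, total reads mapped per
#'   library, `R`).
#' @export
build_count_matrix <- function(assignments, reference,
                               policy = c("whole", "fractional")) {
  policy <- match.arg(policy)
  if (!"library_label" %in% names(assignments))
    stop("assignments must carry a library_label column")
  bad <- setdiff(unique(assignments$library_label), LIB_LABELS)
  if (length(bad) > 0)
    stop(sprintf("unknown library_label: %s", paste(bad, collapse = ", ")))
  counts <- matrix(0, nrow(reference), 4,
                   dimnames = list(reference$cds_id, LIB_LABELS))
  if (nrow(assignments) > 0) {
    w <- rep(1, nrow(assignments))
    if (policy == "fractional") {
      k <- table(assignments$read_id)
      w <- 1 / as.vector(k[assignments$read_id])
    }
    i <- match(assignments$cds_id, reference$cds_id)
    if (anyNA(i)) stop("assignment references a cds_id absent from the reference")
    j <- match(assignments$library_label, LIB_LABELS)
    key <- i + (j - 1L) * nrow(reference)  # column-major linear index
    acc <- rowsum(w, key)
    counts[as.integer(rownames(acc))] <- acc[, 1]
  }
  out <- tibble::tibble(cds_id = reference$cds_id)
  for (lib in LIB_LABELS) out[[paste0("r_", lib)]] <- unname(counts[, lib])
  structure(list(counts = out, totals = colSums(counts)),
            class = "count_matrix")
}
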