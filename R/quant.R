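#' Reads per kilobase per million mapped reads
#'
#' `rpkm = 1e9 * r / (cds_length * R)` where `r` is the mapped-read count
#' of the CDS and `R` the library's total mapped reads. Each library uses
#' its own total; no cross-library averaging.
#'
#' @param r Mapped-read count(s) for the CDS.
#' @param cds_length CDS length(s) in nt (> 0).
#' @param R Total mapped reads of the library.
#' @return RPKM value(s); 0 with a warning when `R == 0`.
#' @export
rpkm <- function(r, cds_length, R) {
  if (any(cds_length <= 0)) stop("cds_length must be > 0")
  if (any(R == 0)) {
    warning("library total R is 0; RPKM undefined, returning 0")
    return(ifelse(R == 0, 0, 1e9 * r / (cds_length * R)))
  }
  1e9 * r / (cds_length * R)
}

#' Transcripts per million
#'
#' Length-normalized rates `r/length` rescaled to sum to one million per
#' library. An all-zero count vector maps to all zeros.
#'
#' @param counts Per-CDS mapped-read counts of one library.
#' @param lengths Per-CDS lengths in nt (> 0).
#' @return TPM vector, summing to 1e6 when any read mapped.
#' @export
tpm_vector <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("lengths must be > 0")
  rate <- counts / lengths
  s <- sum(rate)
  if (s == 0) return(rep(0, length(counts)))
  1e6 * rate / s
}

#' Expression index
#'
#' Mapped reads scaled to the library maximum: `100 * r / r_max`, where
#' `r_max` is the largest mapped-read count of any single CDS in the
#' reference library. The CDS holding the maximum gets exactly 100.
#'
#' @param r Mapped-read count(s).
#' @param r_max Largest per-CDS mapped-read count in the reference library.
#' @return EI value(s) in `[0, 100]`.
#' @export
expression_index <- function(r, r_max) {
  if (length(r_max) != 1 || r_max <= 0)
    stop("r_max must be a single positive count")
  if (any(r < 0) || any(r > r_max)) stop("r must satisfy 0 <= r <= r_max")
  100 * r / r_max
}

#' Pseudocounted normalized read ratio
#'
#' `r1 * R2 / (R1 * (r2 + 1))`: the cross-library enrichment statistic on
#' raw counts, with one read added to the denominator count to avoid
#' division by zero.
#'
#' @param r1,r2 Per-CDS mapped-read counts in libraries 1 and 2.
#' @param R1,R2 Total mapped reads of libraries 1 and 2.
#' @return Ratio value(s).
#' @export
normalized_ratio <- function(r1, R1, r2, R2) {
  if (any(R1 <= 0) || any(R2 <= 0)) stop("library totals must be > 0")
  # double arithmetic: r * R products overflow 32-bit integers
  as.numeric(r1) * as.numeric(R2) / (as.numeric(R1) * (as.numeric(r2) + 1))
}

#' Pseudocounted TPM ratio
#'
#' `tpm_num / (tpm_den + 0.1)`; 0.1 is always added to the denominator to
#' avoid division by zero.
#'
#' @param tpm_num,tpm_den TPM values (>= 0).
#' @return Ratio value(s).
#' @export
tpm_ratio <- function(tpm_num, tpm_den) {
  if (any(tpm_num < 0) || any(tpm_den < 0)) stop("tpm values must be >= 0")
  tpm_num / (tpm_den + 0.1)
}

#' Per-CDS expression table
#'
#' Computes, for every CDS, RPKM and TPM in each of the four libraries, the
#' expression index anchored to the reference library's maximum count
#' (default FSG), and the six directed pseudocounted ratios (both on TPM
#' and as normalized read ratios): FSG/MSG, FSG/FWB, FSG/MWB, FWB/MWB,
#' MSG/MWB, MSG/FWB.
#'
#' @param count_matrix A `count_matrix` from [build_count_matrix()], or a
#'   list with `counts` (tibble `cds_id`, `r_FSG` .. `r_MWB`) and `totals`.
#' @param lengths Per-CDS lengths in nt, aligned with `counts` rows (or a
#'   tibble with `cds_id` and `length`).
#' @param ei_reference Library anchoring the expression index.
#' @return Tibble with `cds_id`, `length`, `r_*`, `rpkm_*`, `tpm_*`, `ei`,
#'   `tpm_<num>_over_<den>` and `nr_<num>_over_<den>` columns.
#' @export
expression_table <- function(count_matrix, lengths, ei_reference = "FSG") {
  counts <- count_matrix$counts
  totals <- count_matrix$totals
  if (is.data.frame(lengths))
    lengths <- lengths$length[match(counts$cds_id, lengths$cds_id)]
  if (length(lengths) != nrow(counts) || anyNA(lengths))
    stop("lengths must provide one length per CDS in the count matrix")
  if (!ei_reference %in% LIB_LABELS)
    stop("ei_reference must be one of FSG, MSG, FWB, MWB")
  out <- tibble::tibble(cds_id = counts$cds_id, length = lengths)
  for (lib in LIB_LABELS) out[[paste0("r_", lib)]] <- counts[[paste0("r_", lib)]]
  for (lib in LIB_LABELS) {
    r <- counts[[paste0("r_", lib)]]
    out[[paste0("rpkm_", lib)]] <- if (totals[[lib]] > 0)
      rpkm(r, lengths, totals[[lib]]) else rep(0, nrow(counts))
    out[[paste0("tpm_", lib)]] <- tpm_vector(r, lengths)
  }
  r_ref <- counts[[paste0("r_", ei_reference)]]
  if (nrow(counts) == 0) {
    out$ei <- numeric(0)
  } else if (max(r_ref) > 0) {
    out$ei <- expression_index(r_ref, max(r_ref))
  } else {
    warning(sprintf("no reads mapped in the EI reference library %s; EI set to NA",
                    ei_reference))
    out$ei <- NA_real_
  }
  for (pair in RATIO_PAIRS) {
    num <- pair[1]; den <- pair[2]
    out[[sprintf("tpm_%s_over_%s", num, den)]] <-
      tpm_ratio(out[[paste0("tpm_", num)]], out[[paste0("tpm_", den)]])
    out[[sprintf("nr_%s_over_%s", num, den)]] <-
      if (totals[[num]] > 0 && totals[[den]] > 0)
        normalized_ratio(counts[[paste0("r_", num)]], totals[[num]],
                         counts[[paste0("r_", den)]], totals[[den]])
      else rep(NA_real_, nrow(counts))
  }
  out
}
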