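#' Per-CDS chi-square test on paired library counts
#'
#' Pearson chi-square (1 df) on the 2x2 table
#' `[[r1, R1 - r1], [r2, R2 - r2]]` contrasting a CDS's mapped reads
#' against the rest of each library. No continuity correction by default
#' (counts are large in the intended regime); Yates' correction is
#' available behind `correct = TRUE`. A zero margin (`r1 + r2 == 0`, or
#' both libraries fully on the CDS) yields statistic 0 and p 1.
#'
#' All arguments are vectorized over CDS.
#'
#' @param r1,r2 Per-CDS mapped-read counts in libraries 1 and 2.
#' @param R1,R2 Total mapped reads of libraries 1 and 2.
#' @param correct Apply Yates' continuity correction.
#' @return Tibble with `statistic` and `p_raw`.
#' @export
chi2_counts <- function(r1, R1, r2, R2, correct = FALSE) {
  if (any(R1 <= 0) || any(R2 <= 0)) stop("library totals must be > 0")
  if (any(r1 < 0) || any(r2 < 0) || any(r1 > R1) || any(r2 > R2))
    stop("counts must satisfy 0 <= r <= R")
  # double arithmetic: the cross products overflow 32-bit integers
  a <- as.numeric(r1); b <- as.numeric(R1 - r1)
  c <- as.numeric(r2); d <- as.numeric(R2 - r2)
  N <- R1 + R2
  num <- abs(a * d - b * c)
  if (correct) num <- pmax(num - N / 2, 0)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  stat <- ifelse(denom > 0, N * num^2 / denom, 0)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  degenerate <- (a + c) == 0 | (b + d) == 0
  stat[degenerate] <- 0
  p[degenerate] <- 1
  tibble::tibble(statistic = stat, p_raw = p)
}

#' Multiple-testing correction
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up adjusted
#' values, order-preserving with the input. Thin, validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be in [0, 1]")
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Salivary-gland enrichment filter
#'
#' A CDS passes when its pooled salivary-vs-whole-body TPM fold is at least
#' `fold_threshold` (inclusive) and its BH-adjusted chi-square q-value is at
#' most `alpha`. The fold is `(tpm_FSG + tpm_MSG) / (tpm_FWB + tpm_MWB +
#' 0.1)`, the pseudocounted TPM ratio of summed salivary over summed
#' whole-body abundance.
#'
#' @param sg_wb_fold Pooled SG/WB TPM fold(s).
#' @param q_bh BH-adjusted p-value(s) of the pooled-count chi-square test.
#' @param fold_threshold Minimum fold (default 10, inclusive).
#' @param alpha Significance level on the BH q-value.
#' @return Logical vector.
#' @export
salivary_filter <- function(sg_wb_fold, q_bh, fold_threshold = 10, alpha = 0.05) {
  sg_wb_fold >= fold_threshold & q_bh <= alpha
}

#' Sex partition of salivary-enriched CDS
#'
#' Among CDS passing the salivary filter: `female_enriched` when the
#' pseudocounted TPM ratio FSG/(MSG+0.1) is at least `fold` (inclusive),
#' `male_enriched` when MSG/(FSG+0.1) is, `shared` otherwise. In the
#' degenerate case where pseudocounts make both ratios pass, the larger
#' ratio wins.
#'
#' @param tpm_fsg,tpm_msg Per-CDS TPM in the female and male SG libraries.
#' @param fold Sex fold threshold (default 5, inclusive).
#' @return Character vector over `female_enriched`, `male_enriched`,
#'   `shared`.
#' @export
sex_partition <- function(tpm_fsg, tpm_msg, fold = 5) {
  f <- tpm_ratio(tpm_fsg, tpm_msg)
  m <- tpm_ratio(tpm_msg, tpm_fsg)
  ifelse(f >= fold & (m < fold | f >= m), "female_enriched",
         ifelse(m >= fold, "male_enriched", "shared"))
}

#' Extreme tissue-specificity screen
#'
#' Flags CDS whose salivary TPM exceeds `threshold`-fold (strictly) the
#' opposite sex's whole-body TPM: female direction FSG/(MWB+0.1), male
#' direction MSG/(FWB+0.1).
#'
#' @param tpm_fsg,tpm_msg,tpm_fwb,tpm_mwb Per-CDS TPM per library.
#' @param threshold Strict ratio threshold (default 1000).
#' @return Tibble with logical `extreme_female`, `extreme_male`.
#' @export
extreme_screen <- function(tpm_fsg, tpm_msg, tpm_fwb, tpm_mwb,
                           threshold = 1000) {
  tibble::tibble(
    extreme_female = tpm_ratio(tpm_fsg, tpm_mwb) > threshold,
    extreme_male = tpm_ratio(tpm_msg, tpm_fwb) > threshold)
}

#' Row-wise Z scores for heatmap display
#'
#' Centers and scales each row (CDS) of a TPM matrix by its mean and sample
#' standard deviation. Constant rows map to all zeros so heatmaps stay
#' well-defined.
#'
#' @param m Numeric matrix (CDS x libraries).
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) == 0) return(m)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Enrichment testing and classification for every CDS
#'
#' Runs the full statistical stage: pooled salivary (FSG+MSG) versus
#' whole-body (FWB+MWB) chi-square per CDS, Bonferroni and
#' Benjamini-Hochberg correction, the tenfold salivary filter, the
#' fivefold sex partition, and the extreme-specificity screen.
#'
#' @param count_matrix A `count_matrix` from [build_count_matrix()].
#' @param expr Expression table from [expression_table()] (same CDS order).
#' @param sg_fold Salivary filter fold threshold (inclusive).
#' @param sex_fold Sex partition fold threshold (inclusive).
#' @param extreme_threshold Extreme screen ratio threshold (strict).
#' @param alpha BH q-value gate of the salivary filter.
#' @param correct Yates continuity correction for the chi-square test.
#' @return Tibble with `cds_id`, `chi2_stat`, `p_raw`, `p_bonferroni`,
#'   `q_bh`, `sg_wb_fold` (pooled TPM fold), `sg_wb_norm_ratio` (pooled
#'   normalized read ratio), `fsg_msg_fold`, `msg_fsg_fold`, `category`
#'   (one of `female_enriched`, `male_enriched`, `shared`,
#'   `not_sg_enriched`), `extreme_female`, `extreme_male`, `extreme`.
#' @export
enrichment_calls <- function(count_matrix, expr, sg_fold = 10, sex_fold = 5,
                             extreme_threshold = 1000, alpha = 0.05,
                             correct = FALSE) {
  counts <- count_matrix$counts
  totals <- count_matrix$totals
  if (!identical(counts$cds_id, expr$cds_id))
    stop("count matrix and expression table must list the same CDS in the same order")
  r_sg <- counts$r_FSG + counts$r_MSG
  r_wb <- counts$r_FWB + counts$r_MWB
  R_sg <- totals[["FSG"]] + totals[["MSG"]]
  R_wb <- totals[["FWB"]] + totals[["MWB"]]
  test <- chi2_counts(r_sg, R_sg, r_wb, R_wb, correct = correct)
  p_bonf <- adjust_pvalues(test$p_raw, "bonferroni")
  q_bh <- adjust_pvalues(test$p_raw, "bh")
  sg_wb_fold <- tpm_ratio(expr$tpm_FSG + expr$tpm_MSG,
                          expr$tpm_FWB + expr$tpm_MWB)
  sg_wb_norm_ratio <- if (R_sg > 0 && R_wb > 0)
    normalized_ratio(r_sg, R_sg, r_wb, R_wb) else rep(NA_real_, nrow(counts))
  passes <- salivary_filter(sg_wb_fold, q_bh, sg_fold, alpha)
  category <- rep("not_sg_enriched", nrow(counts))
  category[passes] <- sex_partition(expr$tpm_FSG[passes], expr$tpm_MSG[passes],
                                    fold = sex_fold)
  ext <- extreme_screen(expr$tpm_FSG, expr$tpm_MSG, expr$tpm_FWB,
                        expr$tpm_MWB, threshold = extreme_threshold)
  tibble::tibble(
    cds_id = counts$cds_id,
    chi2_stat = test$statistic,
    p_raw = test$p_raw,
    p_bonferroni = p_bonf,
    q_bh = q_bh,
    sg_wb_fold = sg_wb_fold,
    sg_wb_norm_ratio = sg_wb_norm_ratio,
    fsg_msg_fold = tpm_ratio(expr$tpm_FSG, expr$tpm_MSG),
    msg_fsg_fold = tpm_ratio(expr$tpm_MSG, expr$tpm_FSG),
    category = category,
    extreme_female = ext$extreme_female,
    extreme_male = ext$extreme_male,
    extreme = ext$extreme_female | ext$extreme_male)
}
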