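#' Relative expression by the 2^-ddCt method
#'
#' Computes the fold change of a target gene between two groups, normalized
#' against a reference gene (in the assay design this package mirrors, the
#' 40S ribosomal protein S7 transcript). Technical duplicates are averaged
#' per biological replicate (set `average_technical = FALSE` to treat them
#' as replicates instead); dCt = Ct_target - Ct_reference per replicate;
#' ddCt = mean dCt(test) - mean dCt(control); the standard error of ddCt
#' combines the two group standard errors in quadrature; the fold change is
#' `2^-ddCt` with the interval `(2^-(ddCt+SE), 2^-(ddCt-SE))`.
#'
#' @param ct_data Tidy tibble with columns `gene`, `group`, `bio_rep`,
#'   `tech_rep`, `ct` (finite, positive).
#' @param target,reference Gene identifiers present in `ct_data`.
#' @param test_group,control_group Group labels present in `ct_data`.
#' @param average_technical Average technical duplicates per biological
#'   replicate before computing replicate statistics.
#' @return One-row tibble: `target`, `test_group`, `control_group`, `ddct`,
#'   `se_ddct` (`NA` with a single replicate), `fold` (= 2^-ddct),
#'   `fold_lo`, `fold_hi`, `n_test`, `n_control`.
#' @export
delta_delta_ct <- function(ct_data, target, reference,
                           test_group, control_group,
                           average_technical = TRUE) {
  need <- c("gene", "group", "bio_rep", "ct")
  if (!all(need %in% names(ct_data)))
    stop("ct_data must have columns gene, group, bio_rep, ct")
  if (any(!is.finite(ct_data$ct)) || any(ct_data$ct <= 0))
    stop("Ct values must be finite and positive")
  for (g in c(target, reference)) if (!any(ct_data$gene == g))
    stop(sprintf("gene '%s' absent from ct_data", g))
  for (g in c(test_group, control_group)) if (!any(ct_data$group == g))
    stop(sprintf("group '%s' absent from ct_data", g))

  dct_group <- function(grp) {
    sub <- ct_data[ct_data$group == grp & ct_data$gene %in% c(target, reference), ]
    if (average_technical) {
      sub <- stats::aggregate(ct ~ gene + bio_rep, data = sub, FUN = mean)
    } else {
      sub$bio_rep <- interaction(sub$bio_rep,
                                 if ("tech_rep" %in% names(sub)) sub$tech_rep else 1)
    }
    tg <- sub[sub$gene == target, ]
    rf <- sub[sub$gene == reference, ]
    m <- merge(tg[, c("bio_rep", "ct")], rf[, c("bio_rep", "ct")],
               by = "bio_rep", suffixes = c("_target", "_reference"))
    if (nrow(m) == 0)
      stop(sprintf("no replicate has both target and reference Ct in group '%s'", grp))
    m$ct_target - m$ct_reference
  }
  dct_t <- dct_group(test_group)
  dct_c <- dct_group(control_group)
  ddct <- mean(dct_t) - mean(dct_c)
  se <- if (length(dct_t) > 1 && length(dct_c) > 1)
    sqrt(sd(dct_t)^2 / length(dct_t) + sd(dct_c)^2 / length(dct_c))
  else NA_real_
  tibble::tibble(
    target = target, test_group = test_group, control_group = control_group,
    ddct = ddct, se_ddct = se, fold = 2^-ddct,
    fold_lo = if (is.na(se)) NA_real_ else 2^-(ddct + se),
    fold_hi = if (is.na(se)) NA_real_ else 2^-(ddct - se),
    n_test = length(dct_t), n_control = length(dct_c))
}

#' Concordance between qPCR and RNA-seq fold estimates
#'
#' Pearson correlation and ordinary least-squares regression of log2
#' RNA-seq folds on log2 qPCR folds, with 95 percent confidence intervals
#' on the fitted coefficients.
#'
#' @param log2_qpcr,log2_rnaseq Paired log2 fold changes (>= 3 pairs, both
#'   with nonzero variance).
#' @return List: `r`, `p_value`, `slope`, `intercept`, `conf_int` (2x2
#'   matrix of 95 percent CIs for intercept and slope), `n`, and `fit` (the
#'   underlying `lm` object, for prediction bands).
#' @export
qpcr_concordance <- function(log2_qpcr, log2_rnaseq) {
  if (length(log2_qpcr) != length(log2_rnaseq))
    stop("inputs must be paired")
  if (length(log2_qpcr) < 3) stop("at least 3 pairs required")
  if (sd(log2_qpcr) == 0 || sd(log2_rnaseq) == 0)
    stop("zero variance in one coordinate; correlation undefined")
  ct <- cor.test(log2_qpcr, log2_rnaseq, method = "pearson")
  fit <- lm(log2_rnaseq ~ log2_qpcr)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       conf_int = confint(fit), n = length(log2_qpcr), fit = fit)
}
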