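#' Configuration for the synthetic four-library experiment
#'
#' Builds and validates the configuration object consumed by
#' [generate_cds_set()] and [synthesize_reads()]. Defaults emulate the
#' sialotranscriptome study design this package targets: four libraries
#' (FSG, MSG, FWB, MWB), 101-nt reads, a roughly 3:1 FSG:MSG sequencing
#' depth reflecting the 3:1 female:male molar pooling of the salivary-gland
#' cDNA libraries, and planted enrichment classes whose fold ranges put
#' every enriched CDS comfortably past the tenfold-salivary and fivefold-sex
#' thresholds (sg folds 25-150, sex folds 25-120).
#'
#' The generative model plants folds directly in TPM space: an enriched CDS
#' receives per-library expected masses `u` (its enriched salivary gland),
#' `u / sex_fold` (the other salivary gland), and `(FSG + MSG) / (2 *
#' sg_fold)` in each whole-body library — whole body is thus the salivary
#' signal diluted `sg_fold`-fold, plus the shared background pool. Enriched
#' masses are scaled so their largest per-library share equals
#' `enriched_mass_fraction`, and background CDS absorb each library's
#' remaining mass in equal parts (so background CDS sit near fold 1 in every
#' comparison).
#'
#' @param n_cds Number of CDS in the reference.
#' @param cds_length_range Length-2 integer vector, nt range for CDS lengths.
#' @param library_depths Named numeric vector of expected read counts, names
#'   exactly `FSG`, `MSG`, `FWB`, `MWB`.
#' @param read_length Read length in nt (>= 26).
#' @param per_base_error_rate Per-base substitution probability in `[0, 0.05)`.
#' @param class_proportions Named numeric vector over
#'   `female_sg_enriched`, `male_sg_enriched`, `shared_sg`, `background`;
#'   must sum to 1.
#' @param fold_ranges Named list with elements `sg` (SG-vs-WB fold interval
#'   for enriched classes), `sex` (sex fold interval for single-sex enriched
#'   classes) and `shared_sex` (FSG/MSG spread for the shared class, applied
#'   in a random direction).
#' @param enriched_mass_fraction Largest per-library mass share given to the
#'   enriched CDS jointly (0-1); the rest goes to background.
#' @param low_quality_tail_fraction Fraction of reads given a low-quality
#'   (Q=2) 3' tail of 1-10 nt, to exercise quality trimming.
#' @param n_duplicates Number of CDS generated as exact copies of earlier
#'   ones (for multi-mapping tests); default 0 keeps sequences distinct.
#' @param rng_seed Integer seed; all randomness in the generator derives
#'   from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cds = 500,
                             cds_length_range = c(300L, 1800L),
                             library_depths = c(FSG = 200000, MSG = 66667,
                                                FWB = 100000, MWB = 100000),
                             read_length = 101L,
                             per_base_error_rate = 0.01,
                             class_proportions = c(female_sg_enriched = 0.115,
                                                   male_sg_enriched = 0.038,
                                                   shared_sg = 0.047,
                                                   background = 0.80),
                             fold_ranges = list(sg = c(25, 150),
                                                sex = c(25, 120),
                                                shared_sex = c(1, 2)),
                             enriched_mass_fraction = 0.5,
                             low_quality_tail_fraction = 0.02,
                             n_duplicates = 0L,
                             rng_seed = 1L) {
  if (!is.numeric(n_cds) || length(n_cds) != 1 || n_cds < 0 || n_cds != round(n_cds))
    stop_config("n_cds", "must be a single non-negative integer")
  if (length(cds_length_range) != 2 || any(cds_length_range < 1) ||
      cds_length_range[1] > cds_length_range[2])
    stop_config("cds_length_range", "must be an increasing pair of positive lengths")
  if (is.null(names(library_depths)) || !setequal(names(library_depths), LIB_LABELS))
    stop_config("library_depths", "names must be exactly FSG, MSG, FWB, MWB")
  if (any(library_depths <= 0))
    stop_config("library_depths", "all depths must be > 0")
  if (read_length < 26)
    stop_config("read_length", "must be >= 26")
  if (per_base_error_rate < 0 || per_base_error_rate >= 0.05)
    stop_config("per_base_error_rate", "must be in [0, 0.05)")
  classes <- c("female_sg_enriched", "male_sg_enriched", "shared_sg", "background")
  if (is.null(names(class_proportions)) || !setequal(names(class_proportions), classes))
    stop_config("class_proportions", "names must cover the four enrichment classes")
  if (any(class_proportions < 0) || abs(sum(class_proportions) - 1) > 1e-9)
    stop_config("class_proportions", "must be non-negative and sum to 1")
  for (fr in c("sg", "sex", "shared_sex")) {
    v <- fold_ranges[[fr]]
    if (is.null(v) || length(v) != 2 || any(v < 1) || v[1] > v[2])
      stop_config("fold_ranges", sprintf("'%s' must be an increasing pair of folds >= 1", fr))
  }
  if (enriched_mass_fraction <= 0 || enriched_mass_fraction >= 1)
    stop_config("enriched_mass_fraction", "must be in (0, 1)")
  if (low_quality_tail_fraction < 0 || low_quality_tail_fraction > 1)
    stop_config("low_quality_tail_fraction", "must be in [0, 1]")
  if (n_duplicates < 0 || n_duplicates >= max(n_cds, 1))
    stop_config("n_duplicates", "must be >= 0 and < n_cds")
  if (!is.numeric(rng_seed) || length(rng_seed) != 1)
    stop_config("rng_seed", "must be a single integer")
  structure(list(
    n_cds = as.integer(n_cds),
    cds_length_range = as.integer(cds_length_range),
    library_depths = library_depths[LIB_LABELS],
    read_length = as.integer(read_length),
    per_base_error_rate = per_base_error_rate,
    class_proportions = class_proportions[classes],
    fold_ranges = fold_ranges,
    enriched_mass_fraction = enriched_mass_fraction,
    low_quality_tail_fraction = low_quality_tail_fraction,
    n_duplicates = as.integer(n_duplicates),
    rng_seed = as.integer(rng_seed)
  ), class = "synthetic_config")
}

# deterministic class counts: floor allocation, remainder to the classes
# with the largest fractional parts
class_counts <- function(prop, n) {
  raw <- prop * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

#' Generate a synthetic CDS reference with planted enrichment truth
#'
#' Draws `n_cds` random nucleotide sequences (uniform A/C/G/T) in the
#' configured length range, assigns each an enrichment class, and builds the
#' per-library expected relative abundances realizing the planted folds (see
#' [synthetic_config()] for the generative model). When `n_duplicates > 0`
#' the last `n_duplicates` CDS are exact sequence copies of the first ones,
#' for exercising multi-mapping.
#'
#' @param config A [synthetic_config()] object.
#' @return A list with elements `cds` (tibble: `cds_id`, `sequence`,
#'   `length`) and `truth` (tibble: `cds_id`, `class_label`, `true_sg_fold`,
#'   `true_sex_fold`, and per-library expected abundance columns
#'   `abund_FSG` .. `abund_MWB`, each column summing to 1).
#' @export
generate_cds_set <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop("config must be created by synthetic_config()")
  n <- config$n_cds
  if (n == 0) {
    return(list(
      cds = tibble::tibble(cds_id = character(), sequence = character(),
                           length = integer()),
      truth = tibble::tibble(cds_id = character(), class_label = character(),
                             true_sg_fold = numeric(), true_sex_fold = numeric(),
                             abund_FSG = numeric(), abund_MSG = numeric(),
                             abund_FWB = numeric(), abund_MWB = numeric())
    ))
  }
  with_seed(config$rng_seed, {
    ids <- sprintf("CDS%05d", seq_len(n))
    lens <- sample(seq(config$cds_length_range[1], config$cds_length_range[2]),
                   n, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    if (config$n_duplicates > 0) {
      src <- seq_len(config$n_duplicates)
      dst <- n - config$n_duplicates + src
      seqs[dst] <- seqs[src]
      lens[dst] <- lens[src]
    }

    classes <- names(config$class_proportions)
    cnt <- class_counts(config$class_proportions, n)
    label <- sample(rep(classes, times = cnt))

    sg_fold <- rep(1, n)
    sex_fold <- rep(1, n)
    enriched <- label != "background"
    ne <- sum(enriched)
    if (ne > 0) {
      sg_fold[enriched] <- runif(ne, config$fold_ranges$sg[1], config$fold_ranges$sg[2])
      single <- label %in% c("female_sg_enriched", "male_sg_enriched")
      sex_fold[single] <- runif(sum(single), config$fold_ranges$sex[1],
                                config$fold_ranges$sex[2])
      sh <- label == "shared_sg"
      if (any(sh)) {
        spread <- runif(sum(sh), config$fold_ranges$shared_sex[1],
                        config$fold_ranges$shared_sex[2])
        flip <- sample(c(TRUE, FALSE), sum(sh), replace = TRUE)
        sex_fold[sh] <- ifelse(flip, spread, 1 / spread)
      }
    }

    # per-library unnormalized masses
    A <- matrix(0, n, 4, dimnames = list(NULL, LIB_LABELS))
    if (ne > 0) {
      u <- runif(n, 0.5, 1.5)
      f <- label == "female_sg_enriched"
      m <- label == "male_sg_enriched"
      s <- label == "shared_sg"
      A[f, "FSG"] <- u[f];             A[f, "MSG"] <- u[f] / sex_fold[f]
      A[m, "MSG"] <- u[m];             A[m, "FSG"] <- u[m] / sex_fold[m]
      A[s, "FSG"] <- u[s] * sqrt(sex_fold[s])
      A[s, "MSG"] <- u[s] / sqrt(sex_fold[s])
      wb <- (A[enriched, "FSG"] + A[enriched, "MSG"]) / (2 * sg_fold[enriched])
      A[enriched, "FWB"] <- wb
      A[enriched, "MWB"] <- wb
    }
    n_bg <- n - ne
    if (n_bg > 0) {
      if (ne > 0) {
        scale <- config$enriched_mass_fraction / max(colSums(A))
        A <- A * scale
      }
      bg_share <- (1 - colSums(A)) / n_bg
      A[label == "background", ] <- matrix(bg_share, n_bg, 4, byrow = TRUE)
    } else {
      # no background pool to absorb slack: normalize each library directly
      A <- sweep(A, 2, colSums(A), "/")
    }

    truth <- tibble::tibble(
      cds_id = ids, class_label = label,
      true_sg_fold = sg_fold, true_sex_fold = sex_fold,
      abund_FSG = A[, "FSG"], abund_MSG = A[, "MSG"],
      abund_FWB = A[, "FWB"], abund_MWB = A[, "MWB"])
    list(cds = tibble::tibble(cds_id = ids, sequence = seqs,
                              length = as.integer(lens)),
         truth = truth)
  })
}

#' Synthesize the four FASTQ read libraries from planted truth
#'
#' Draws reads per library by multinomial allocation over the truth's
#' per-library abundances, uniform start positions, both strands with
#' probability 1/2, and independent per-base substitution errors. Base
#' qualities are high (Q=35) except for an optional injected low-quality
#' (Q=2) 3' tail on a configured fraction of reads. CDS shorter than the
#' read length are excluded from sampling with a warning.
#'
#' @param cds_set Result of [generate_cds_set()] (or a compatible list with
#'   `cds` tibble).
#' @param truth Truth tibble covering every CDS (defaults to
#'   `cds_set$truth`).
#' @param config The [synthetic_config()] used for generation.
#' @return A list with `reads` (named list of per-library tibbles:
#'   `read_id`, `sequence`, `quality`) and `expected_counts` (tibble:
#'   `cds_id` plus `exp_FSG` .. `exp_MWB`, the multinomial expectations; they
#'   sum to each library's depth).
#' @export
synthesize_reads <- function(cds_set, truth = cds_set$truth, config) {
  cds <- cds_set$cds
  if (!all(cds$cds_id %in% truth$cds_id))
    stop("truth must cover every CDS in the reference")
  truth <- truth[match(cds$cds_id, truth$cds_id), ]
  rl <- config$read_length
  eligible <- cds$length >= rl
  if (any(!eligible))
    warning(sprintf("%d CDS shorter than the read length (%d nt) excluded from sampling",
                    sum(!eligible), rl))

  abund <- as.matrix(truth[, paste0("abund_", LIB_LABELS)])
  colnames(abund) <- LIB_LABELS
  abund[!eligible, ] <- 0

  expected <- tibble::tibble(cds_id = cds$cds_id)
  for (lib in LIB_LABELS) {
    p <- abund[, lib]
    tot <- sum(p)
    expected[[paste0("exp_", lib)]] <-
      if (tot > 0) config$library_depths[[lib]] * p / tot else rep(0, nrow(cds))
  }

  reads <- with_seed(config$rng_seed + 1L, {
    out <- list()
    for (lib in LIB_LABELS) {
      depth <- round(config$library_depths[[lib]])
      p <- abund[, lib]
      if (sum(p) == 0 || depth == 0) {
        out[[lib]] <- tibble::tibble(read_id = character(),
                                     sequence = character(),
                                     quality = character())
        next
      }
      counts <- as.vector(rmultinom(1, depth, p))
      idx <- rep.int(seq_len(nrow(cds)), counts)
      nr <- length(idx)
      start <- floor(runif(nr) * (cds$length[idx] - rl + 1)) + 1L
      strand <- sample(c("+", "-"), nr, replace = TRUE)
      seqs <- substring(cds$sequence[idx], start, start + rl - 1L)
      neg <- strand == "-"
      if (any(neg)) {
        seqs[neg] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(seqs[neg])))
      }
      # substitution errors: per-read error counts, then vectorized rounds
      nerr <- rbinom(nr, rl, config$per_base_error_rate)
      if (any(nerr > 0)) {
        for (k in seq_len(max(nerr))) {
          sel <- which(nerr >= k)
          pos <- sample.int(rl, length(sel), replace = TRUE)
          old <- substring(seqs[sel], pos, pos)
          shift <- sample.int(3, length(sel), replace = TRUE)
          base_idx <- (match(old, c("A", "C", "G", "T")) - 1L + shift) %% 4L + 1L
          substring(seqs[sel], pos, pos) <- c("A", "C", "G", "T")[base_idx]
        }
      }
      qual <- rep(strrep(rawToChar(as.raw(35 + 33)), rl), nr)
      if (config$low_quality_tail_fraction > 0 && nr > 0) {
        ntail <- rbinom(1, nr, config$low_quality_tail_fraction)
        if (ntail > 0) {
          tsel <- sample.int(nr, ntail)
          tlen <- sample.int(10, ntail, replace = TRUE)
          qual[tsel] <- paste0(strrep(rawToChar(as.raw(35 + 33)), rl - tlen),
                               strrep(rawToChar(as.raw(2 + 33)), tlen))
        }
      }
      out[[lib]] <- tibble::tibble(
        read_id = sprintf("%s:%07d:%s:%s:%d", lib, seq_len(nr),
                          cds$cds_id[idx], strand, start),
        sequence = seqs, quality = qual)
    }
    out
  })
  list(reads = reads, expected_counts = expected)
}

#' Generate a full synthetic experiment in one call
#'
#' Convenience wrapper running [generate_cds_set()] then
#' [synthesize_reads()].
#'
#' @inheritParams generate_cds_set
#' @return A list with `cds`, `truth`, `reads`, `expected_counts`.
#' @export
simulate_libraries <- function(config = synthetic_config()) {
  ref <- generate_cds_set(config)
  if (nrow(ref$cds) == 0)
    return(c(ref, list(reads = NULL, expected_counts = NULL)))
  syn <- synthesize_reads(ref, ref$truth, config)
  c(ref, syn)
}
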