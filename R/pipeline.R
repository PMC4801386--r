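#' Pipeline run configuration
#'
#' Bundles every stage parameter of the four-library enrichment pipeline.
#' In synthetic mode inputs are generated by the [synthetic_config()]
#' generator; otherwise `reference_fasta` and the four `fastq` paths must
#' point to existing files.
#'
#' @param synthetic Generate inputs with [simulate_libraries()].
#' @param synth A [synthetic_config()] (synthetic mode only).
#' @param reference_fasta Path to the CDS FASTA (real-input mode).
#' @param fastq Named character vector of FASTQ paths, names exactly
#'   `FSG`, `MSG`, `FWB`, `MWB` (real-input mode).
#' @param trim_quality Phred threshold for 3' trimming.
#' @param min_read_length Minimum read length after trimming.
#' @param params A [map_params()] object for the mapper.
#' @param multimap_policy Count policy for tied assignments
#'   (see [build_count_matrix()]).
#' @param ei_reference Library anchoring the expression index.
#' @param sg_fold,sex_fold,extreme_threshold,alpha Classification
#'   thresholds (see [enrichment_calls()]).
#' @param rng_seed Seed forwarded to the generator in synthetic mode.
#' @return A list of class `run_config`.
#' @export
run_config <- function(synthetic = TRUE,
                       synth = synthetic_config(rng_seed = rng_seed),
                       reference_fasta = NULL, fastq = NULL,
                       trim_quality = 13L, min_read_length = 25L,
                       params = map_params(),
                       multimap_policy = "whole",
                       ei_reference = "FSG",
                       sg_fold = 10, sex_fold = 5, extreme_threshold = 1000,
                       alpha = 0.05, rng_seed = 1L) {
  if (!synthetic) {
    if (is.null(reference_fasta) || is.null(fastq))
      stop("non-synthetic runs need reference_fasta and fastq paths")
    if (is.null(names(fastq)) || !setequal(names(fastq), LIB_LABELS))
      stop_config("fastq", "names must be exactly FSG, MSG, FWB, MWB")
  }
  stopifnot(trim_quality >= 0, min_read_length >= 1,
            sg_fold > 0, sex_fold > 0, extreme_threshold > 0,
            alpha > 0, alpha <= 1)
  structure(list(synthetic = synthetic, synth = synth,
                 reference_fasta = reference_fasta, fastq = fastq,
                 trim_quality = as.integer(trim_quality),
                 min_read_length = as.integer(min_read_length),
                 params = params, multimap_policy = multimap_policy,
                 ei_reference = ei_reference,
                 sg_fold = sg_fold, sex_fold = sex_fold,
                 extreme_threshold = extreme_threshold, alpha = alpha,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

stage_log <- function(stage, t0, ...) {
  message(sprintf("[%s] %5.1fs %s", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  sprintf(...)))
}

#' Run the full enrichment pipeline
#'
#' Executes simulate (synthetic mode) or load -> trim -> map -> quantify ->
#' test/classify -> summarize, writing `counts.tsv`, `totals.tsv`,
#' `expression.tsv`, `enrichment.tsv`, `zscores.tsv`, `summary.tsv` and a
#' `manifest.json` run manifest to `out_dir` (synthetic mode additionally
#' writes `cds.fasta`, the four FASTQ libraries, `truth.tsv` and
#' `expected_counts.tsv`). Per-stage record counts and timings are logged
#' to standard error. Deterministic given the configuration seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @return Invisibly, a list: `reference`, `truth` (synthetic mode),
#'   `count_matrix`, `expression`, `calls`, `zscores`, `summary`,
#'   `trim_stats`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  t0 <- Sys.time()
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  wr <- function(x, name) if (!is.null(out_dir))
    write_tsv_file(x, file.path(out_dir, name))

  truth <- NULL
  if (config$synthetic) {
    sim <- simulate_libraries(config$synth)
    reference <- sim$cds
    truth <- sim$truth
    reads <- lapply(LIB_LABELS, function(lib) {
      r <- sim$reads[[lib]]
      r$library_label <- lib
      r
    })
    reads <- dplyr::bind_rows(reads)
    if (!is.null(out_dir)) {
      write_cds_fasta(reference, file.path(out_dir, "cds.fasta"))
      for (lib in LIB_LABELS)
        write_fastq_library(sim$reads[[lib]],
                            file.path(out_dir, paste0(lib, ".fastq")))
      wr(truth, "truth.tsv")
      wr(sim$expected_counts, "expected_counts.tsv")
    }
    stage_log("simulate", t0, "%d CDS, %d reads", nrow(reference), nrow(reads))
  } else {
    reference <- read_cds_fasta(config$reference_fasta)
    reads <- dplyr::bind_rows(lapply(LIB_LABELS, function(lib)
      read_fastq_library(config$fastq[[lib]], lib)))
    stage_log("load", t0, "%d CDS, %d reads", nrow(reference), nrow(reads))
  }

  trimmed <- trim_reads(reads, threshold = config$trim_quality,
                        min_length = config$min_read_length)
  trim_stats <- c(n_input = attr(trimmed, "n_input"),
                  n_dropped = attr(trimmed, "n_dropped"))
  stage_log("trim", t0, "%d reads kept, %d dropped",
            nrow(trimmed), trim_stats[["n_dropped"]])

  assignments <- map_reads(trimmed, reference, config$params)
  stage_log("map", t0, "%d assignments for %d mapped reads",
            nrow(assignments), length(unique(assignments$read_id)))

  cm <- build_count_matrix(assignments, reference,
                           policy = config$multimap_policy)
  wr(cm$counts, "counts.tsv")
  wr(tibble::tibble(library_label = names(cm$totals), R = unname(cm$totals)),
     "totals.tsv")

  expr <- expression_table(cm, reference, ei_reference = config$ei_reference)
  wr(expr, "expression.tsv")
  stage_log("quant", t0, "%d CDS quantified", nrow(expr))

  calls <- enrichment_calls(cm, expr, sg_fold = config$sg_fold,
                            sex_fold = config$sex_fold,
                            extreme_threshold = config$extreme_threshold,
                            alpha = config$alpha)
  z <- zscore_rows(as.matrix(expr[, paste0("tpm_", LIB_LABELS)]))
  rownames(z) <- expr$cds_id
  if (!is.null(out_dir)) {
    ztab <- tibble::tibble(cds_id = expr$cds_id)
    for (lib in LIB_LABELS) ztab[[paste0("z_", lib)]] <- z[, paste0("tpm_", lib)]
    wr(ztab, "zscores.tsv")
  }
  wr(calls, "enrichment.tsv")
  stage_log("enrich", t0, "%d CDS pass the salivary filter",
            sum(calls$category != "not_sg_enriched"))

  summ <- category_summary(expr, calls)
  wr(summ, "summary.tsv")

  if (!is.null(out_dir)) {
    manifest <- list(
      package_version = as.character(utils::packageVersion("sialoquant")),
      synthetic = config$synthetic, rng_seed = config$rng_seed,
      thresholds = list(trim_quality = config$trim_quality,
                        min_read_length = config$min_read_length,
                        word_size = config$params$word_size,
                        min_identity = config$params$min_identity,
                        max_hits = config$params$max_hits,
                        sg_fold = config$sg_fold, sex_fold = config$sex_fold,
                        extreme_threshold = config$extreme_threshold,
                        alpha = config$alpha),
      n_cds = nrow(reference), n_reads = trim_stats[["n_input"]],
      totals = as.list(cm$totals),
      categories = as.list(table(calls$category)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(reference = reference, truth = truth, count_matrix = cm,
                 expression = expr, calls = calls, zscores = z,
                 summary = summ, trim_stats = trim_stats))
}

#' Per-category summary of salivary-enriched CDS
#'
#' Mirrors the structure of class-summary tables: per category of the sex
#' partition, the CDS count, mean TPM per library, and the female/male TPM
#' comparison computed both ways - as the mean of per-CDS pseudocounted
#' ratios (`fsg_msg_mean_of_ratios`) and as the ratio of the class mean
#' TPMs (`fsg_msg_ratio_of_means`). The two differ whenever per-CDS ratios
#' are heterogeneous, which is why both are emitted and labeled.
#'
#' @param expr Expression table from [expression_table()].
#' @param calls Calls from [enrichment_calls()] (same CDS order).
#' @return Tibble, one row per category present among salivary-enriched
#'   CDS: `category`, `n`, `mean_tpm_FSG` .. `mean_tpm_MWB`,
#'   `fsg_msg_mean_of_ratios`, `fsg_msg_ratio_of_means`.
#' @export
category_summary <- function(expr, calls) {
  stopifnot(identical(expr$cds_id, calls$cds_id))
  keep <- calls$category != "not_sg_enriched"
  cats <- c("female_enriched", "shared", "male_enriched")
  rows <- lapply(cats, function(cat) {
    sel <- keep & calls$category == cat
    if (!any(sel)) return(NULL)
    row <- tibble::tibble(category = cat, n = sum(sel))
    for (lib in LIB_LABELS)
      row[[paste0("mean_tpm_", lib)]] <- mean(expr[[paste0("tpm_", lib)]][sel])
    row$fsg_msg_mean_of_ratios <- mean(calls$fsg_msg_fold[sel])
    row$fsg_msg_ratio_of_means <-
      tpm_ratio(mean(expr$tpm_FSG[sel]), mean(expr$tpm_MSG[sel]))
    row
  })
  dplyr::bind_rows(rows)
}

#' Confusion matrix and recovery rates against planted truth
#'
#' Compares enrichment calls to the synthetic generator's planted classes.
#' Planted classes map to expected calls as: `female_sg_enriched` ->
#' `female_enriched`, `male_sg_enriched` -> `male_enriched`, `shared_sg` ->
#' `shared`, `background` -> `not_sg_enriched`.
#'
#' @param truth Truth tibble from [generate_cds_set()].
#' @param calls Calls from [enrichment_calls()].
#' @return List: `confusion` (planted class x called category table),
#'   `per_class` (tibble with `class_label`, `n`, `sensitivity`,
#'   `specificity`).
#' @export
recovery_report <- function(truth, calls) {
  if (!setequal(truth$cds_id, calls$cds_id))
    stop("truth and calls must cover the same CDS identifiers")
  calls <- calls[match(truth$cds_id, calls$cds_id), ]
  expected <- c(female_sg_enriched = "female_enriched",
                male_sg_enriched = "male_enriched",
                shared_sg = "shared",
                background = "not_sg_enriched")
  confusion <- table(planted = truth$class_label, called = calls$category)
  per_class <- lapply(names(expected), function(cl) {
    pos <- truth$class_label == cl
    if (!any(pos)) return(NULL)
    hit <- calls$category[pos] == expected[[cl]]
    neg <- !pos
    tn <- if (any(neg)) mean(calls$category[neg] != expected[[cl]]) else NA_real_
    tibble::tibble(class_label = cl, n = sum(pos),
                   sensitivity = mean(hit), specificity = tn)
  })
  list(confusion = confusion, per_class = dplyr::bind_rows(per_class))
}
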