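test_that("configuration validation names the offending field", {
  expect_error(synthetic_config(n_cds = -1), "n_cds")
  expect_error(synthetic_config(per_base_error_rate = 0.05), "per_base_error_rate")
  expect_error(synthetic_config(read_length = 20), "read_length")
  expect_error(synthetic_config(library_depths = c(FSG = 10, MSG = 10, FWB = 10)),
               "library_depths")
  expect_error(synthetic_config(class_proportions = c(
    female_sg_enriched = 0.5, male_sg_enriched = 0.5,
    shared_sg = 0.5, background = 0.5)), "class_proportions")
})

test_that("empty and degenerate CDS sets are handled", {
  empty <- generate_cds_set(synthetic_config(n_cds = 0))
  expect_identical(nrow(empty$cds), 0L)
  expect_identical(nrow(empty$truth), 0L)

  all_female <- generate_cds_set(synthetic_config(
    n_cds = 12, rng_seed = 3,
    class_proportions = c(female_sg_enriched = 1, male_sg_enriched = 0,
                          shared_sg = 0, background = 0)))
  expect_true(all(all_female$truth$class_label == "female_sg_enriched"))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_cds = 30, rng_seed = 11,
                          library_depths = c(FSG = 600, MSG = 200,
                                             FWB = 400, MWB = 400))
  a <- simulate_libraries(cfg)
  b <- simulate_libraries(cfg)
  expect_identical(a$cds, b$cds)
  expect_identical(a$truth, b$truth)
  expect_identical(a$reads, b$reads)
})

test_that("fixed seed gives byte-identical FASTQ output", {
  cfg <- synthetic_config(n_cds = 10, rng_seed = 5,
                          library_depths = c(FSG = 150, MSG = 50,
                                             FWB = 100, MWB = 100))
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq_library(simulate_libraries(cfg)$reads$FSG, f1)
  write_fastq_library(simulate_libraries(cfg)$reads$FSG, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("expected counts sum to the configured depth and truth folds are planted", {
  cfg <- synthetic_config(n_cds = 50, rng_seed = 9)
  ref <- generate_cds_set(cfg)
  syn <- synthesize_reads(ref, ref$truth, cfg)
  for (lib in library_labels()) {
    expect_equal(sum(syn$expected_counts[[paste0("exp_", lib)]]),
                 unname(cfg$library_depths[[lib]]), tolerance = 1e-9)
  }
  tr <- ref$truth
  enr <- tr$class_label %in% c("female_sg_enriched", "male_sg_enriched")
  expect_true(all(tr$true_sg_fold[enr] >= 25))
  expect_true(all(tr$true_sex_fold[enr] >= 25))
  # planted SG/WB fold is exact in relative-abundance space
  got <- (tr$abund_FSG[enr] + tr$abund_MSG[enr]) /
    (tr$abund_FWB[enr] + tr$abund_MWB[enr])
  expect_equal(got, tr$true_sg_fold[enr], tolerance = 1e-9)
})

test_that("zero-noise reads are exact substrings of their source CDS", {
  cfg <- synthetic_config(
    n_cds = 1, cds_length_range = c(300, 300), rng_seed = 2,
    per_base_error_rate = 0, low_quality_tail_fraction = 0,
    class_proportions = c(female_sg_enriched = 0, male_sg_enriched = 0,
                          shared_sg = 0, background = 1),
    library_depths = c(FSG = 10, MSG = 10, FWB = 10, MWB = 10))
  sim <- simulate_libraries(cfg)
  expect_identical(nrow(sim$reads$FSG), 10L)
  cds <- sim$cds$sequence[1]
  both <- c(cds, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cds))))
  for (s in sim$reads$FSG$sequence) {
    expect_true(any(vapply(both, function(x) grepl(s, x, fixed = TRUE),
                           logical(1))))
  }
})

test_that("a planted sex fold of 25 is recovered in depth-adjusted expected and empirical counts", {
  cfg <- synthetic_config(
    n_cds = 20, rng_seed = 13, per_base_error_rate = 0,
    low_quality_tail_fraction = 0,
    fold_ranges = list(sg = c(40, 40), sex = c(25, 25), shared_sex = c(1, 1)),
    library_depths = c(FSG = 10000, MSG = 10000, FWB = 2000, MWB = 2000))
  ref <- generate_cds_set(cfg)
  syn <- synthesize_reads(ref, ref$truth, cfg)
  fem <- which(ref$truth$class_label == "female_sg_enriched")
  expect_gt(length(fem), 0)
  i <- fem[1]
  exp_ratio <- syn$expected_counts$exp_FSG[i] / syn$expected_counts$exp_MSG[i]
  # equal depths here, so the depth-adjusted expectation is the planted fold
  expect_equal(exp_ratio, 25, tolerance = 1e-9)
  count_in <- function(lib) sum(grepl(paste0(":", ref$cds$cds_id[i], ":"),
                                      syn$reads[[lib]]$read_id))
  nf <- count_in("FSG"); nm <- count_in("MSG")
  sd_f <- sqrt(syn$expected_counts$exp_FSG[i])
  expect_lt(abs(nf - syn$expected_counts$exp_FSG[i]), 3 * sd_f + 1)
  expect_lt(abs(nm - syn$expected_counts$exp_MSG[i]),
            3 * sqrt(syn$expected_counts$exp_MSG[i]) + 1)
  expect_gt(nf / max(nm, 1), 10)  # far from parity even with noise
})

test_that("empirical counts at zero error match multinomial expectation within 4 SDs", {
  cfg <- synthetic_config(
    n_cds = 25, rng_seed = 17, per_base_error_rate = 0,
    low_quality_tail_fraction = 0,
    library_depths = c(FSG = 5000, MSG = 2000, FWB = 3000, MWB = 3000))
  ref <- generate_cds_set(cfg)
  syn <- synthesize_reads(ref, ref$truth, cfg)
  for (lib in library_labels()) {
    e <- syn$expected_counts[[paste0("exp_", lib)]]
    src <- sub("^[A-Z]+:\\d+:([^:]+):.*$", "\\1", syn$reads[[lib]]$read_id)
    obs <- as.vector(table(factor(src, levels = ref$cds$cds_id)))
    p <- e / sum(e)
    sds <- sqrt(sum(e) * p * (1 - p))
    expect_true(all(abs(obs - e) <= 4 * sds + 1))
  }
})

test_that("CDS shorter than the read length are excluded with a warning", {
  cfg <- synthetic_config(n_cds = 5, cds_length_range = c(120, 300),
                          rng_seed = 21,
                          library_depths = c(FSG = 200, MSG = 100,
                                             FWB = 100, MWB = 100))
  ref <- generate_cds_set(cfg)
  ref$cds$sequence[2] <- substr(ref$cds$sequence[2], 1, 50)
  ref$cds$length[2] <- 50L
  expect_warning(syn <- synthesize_reads(ref, ref$truth, cfg),
                 "shorter than the read length")
  expect_equal(syn$expected_counts$exp_FSG[2], 0)
  expect_false(any(grepl(ref$cds$cds_id[2], syn$reads$FSG$read_id)))
})
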