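test_that("quality trimming removes low-quality 3' tails and drops short reads", {
  r <- read_tbl(
    c(strrep("A", 101), strrep("C", 101), strrep("G", 30)),
    quality = c(qual_string(rep(30, 101)),
                qual_string(c(rep(30, 91), rep(2, 10))),
                qual_string(c(rep(30, 20), rep(2, 10)))))
  out <- trim_reads(r, threshold = 13, min_length = 25)
  expect_identical(nrow(out), 2L)
  expect_identical(nchar(out$sequence), c(101L, 91L))
  expect_identical(nchar(out$quality), c(101L, 91L))
  expect_identical(attr(out, "n_dropped"), 1L)

  # internal low-quality bases are not trimmed in trim mode
  mid <- read_tbl("A", quality = qual_string(c(rep(30, 40), 2, rep(30, 60))))
  mid$sequence <- strrep("T", 101)
  expect_identical(nchar(trim_reads(mid)$sequence), 101L)
  # but discard mode drops the whole read
  expect_identical(nrow(trim_reads(mid, mode = "discard")), 0L)
})

test_that("an exact unique substring maps with identity 100 and no gaps", {
  withr::with_seed(101, {
    ref <- random_reference(5, c(200, 300))
    rd <- read_tbl(make_read(ref$sequence[3], 40, 60))
    asn <- map_reads(rd, ref)
    expect_identical(nrow(asn), 1L)
    expect_identical(asn$cds_id, ref$cds_id[3])
    expect_equal(asn$identity, 100)
    expect_identical(asn$gaps, 0L)
    expect_identical(asn$strand, "+")
    expect_equal(asn$score, 120)  # 60 matches at +2
  })
})

test_that("the 95 percent identity filter admits 4 but not 6 substitutions in a 101-nt read", {
  withr::with_seed(102, {
    ref <- random_reference(4, c(300, 400))
    # substitutions confined to the 3' half so an exact 25-mer seed remains
    r4 <- read_tbl(make_read(ref$sequence[1], 10, 101, subs = c(60, 70, 80, 90)))
    r6 <- read_tbl(make_read(ref$sequence[1], 10, 101,
                             subs = c(55, 62, 70, 80, 90, 97)))
    a4 <- map_reads(r4, ref)
    expect_identical(nrow(a4), 1L)
    expect_equal(a4$identity, 100 * 97 / 101)
    expect_identical(nrow(map_reads(r6, ref)), 0L)
  })
})

test_that("a read matching 6 identical CDS keeps the 5 lexicographically smallest", {
  withr::with_seed(103, {
    base <- random_seq(250)
    ref <- tibble::tibble(cds_id = sprintf("DUP%02d", 6:1),  # unsorted on purpose
                          sequence = base, length = 250L)
    rd <- read_tbl(make_read(base, 30, 80))
    asn <- map_reads(rd, ref)
    expect_identical(nrow(asn), 5L)
    expect_identical(sort(asn$cds_id), sprintf("DUP%02d", 1:5))
    expect_true(all(asn$score == asn$score[1]))
  })
})

test_that("reverse-complement reads map to the same CDS with flipped strand", {
  withr::with_seed(104, {
    ref <- random_reference(6, c(200, 350))
    fwd <- make_read(ref$sequence[2], 25, 70, subs = c(50, 60))
    rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
    a_f <- map_reads(read_tbl(fwd), ref)
    a_r <- map_reads(read_tbl(rev), ref)
    expect_identical(a_f$cds_id, a_r$cds_id)
    expect_identical(a_f$score, a_r$score)
    expect_identical(a_f$identity, a_r$identity)
    expect_identical(a_f$strand, "+")
    expect_identical(a_r$strand, "-")
  })
})

test_that("single gaps up to length 3 are aligned, longer ones are not", {
  withr::with_seed(105, {
    ref <- random_reference(3, c(300, 400))
    s <- ref$sequence[1]
    # read with a 2-nt deletion relative to the reference
    del2 <- paste0(substr(s, 20, 69), substr(s, 72, 121))  # 100 nt
    a <- map_reads(read_tbl(del2), ref)
    expect_identical(nrow(a), 1L)
    expect_identical(a$gaps, 1L)
    expect_identical(a$gap_len, 2L)
    expect_equal(a$identity, 100 * 100 / 102)
    # a 6-nt deletion cannot be bridged by one gap of length <= 3;
    # the best one-segment alignment fails the identity filter
    del6 <- paste0(substr(s, 20, 69), substr(s, 76, 125))
    expect_identical(nrow(map_reads(read_tbl(del6), ref)), 0L)
  })
})

test_that("raising the identity threshold never increases assignments", {
  withr::with_seed(106, {
    ref <- random_reference(8, c(150, 300))
    seqs <- vapply(1:60, function(i) {
      ci <- sample(8, 1)
      len <- sample(50:90, 1)
      start <- sample(nchar(ref$sequence[ci]) - len + 1, 1)
      nsub <- sample(0:5, 1)
      make_read(ref$sequence[ci], start, len,
                subs = if (nsub > 0) sample(len, nsub) else integer(0))
    }, character(1))
    rd <- read_tbl(seqs, ids = sprintf("r%03d", 1:60))
    n_prev <- Inf
    for (thr in c(90, 95, 98, 100)) {
      n <- nrow(map_reads(rd, ref, map_params(min_identity = thr)))
      expect_lte(n, n_prev)
      n_prev <- n
    }
  })
})

test_that("count matrix applies whole-count and fractional policies", {
  ref <- tibble::tibble(cds_id = c("A", "B"), sequence = c("", ""), length = 0L)
  asn <- tibble::tibble(read_id = c("r1", "r1", "r2"),
                        cds_id = c("A", "B", "A"),
                        library_label = c("FSG", "FSG", "MSG"))
  cm <- build_count_matrix(asn, ref)
  expect_equal(cm$counts$r_FSG, c(1, 1))
  expect_equal(unname(cm$totals["FSG"]), 2)  # tied read counts twice
  expect_equal(unname(cm$totals["MSG"]), 1)
  frac <- build_count_matrix(asn, ref, policy = "fractional")
  expect_equal(frac$counts$r_FSG, c(0.5, 0.5))
  expect_equal(unname(frac$totals["FSG"]), 1)

  empty <- build_count_matrix(asn[0, ], ref)
  expect_true(all(empty$counts$r_FSG == 0))
  expect_true(all(empty$totals == 0))
  expect_error(build_count_matrix(
    tibble::tibble(read_id = "r", cds_id = "A", library_label = "XXX"), ref),
    "unknown library_label")
})

test_that("library totals equal the column sums of the count matrix", {
  withr::with_seed(107, {
    ref <- random_reference(6, c(200, 300))
    seqs <- vapply(1:40, function(i) {
      ci <- sample(6, 1)
      make_read(ref$sequence[ci], sample(100, 1), 60)
    }, character(1))
    rd <- read_tbl(seqs, library_label = sample(library_labels(), 40, TRUE))
    cm <- build_count_matrix(map_reads(rd, ref), ref)
    for (lib in library_labels())
      expect_equal(unname(cm$totals[lib]), sum(cm$counts[[paste0("r_", lib)]]))
  })
})
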