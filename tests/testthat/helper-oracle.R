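# Reference aligner: an independent, brute-force R implementation of the
# mapping rule, used to validate the compiled seed-and-extend mapper.
# Same contract as map_reads(): whole read inside the CDS, candidate
# diagonals are those carrying an exact word-size match, at most one gap
# (length 1..max_gap_len) with one segment on a seeded diagonal, identity
# and score computed over alignment columns.

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# all (overlapping) occurrence start positions of kmers of `seq`, 1-based
oracle_kmer_positions <- function(seq, w) {
  L <- nchar(seq)
  if (L < w) return(data.frame(kmer = character(), pos = integer()))
  pos <- seq_len(L - w + 1)
  data.frame(kmer = substring(seq, pos, pos + w - 1), pos = pos,
             stringsAsFactors = FALSE)
}

# cumulative matches of read chars vs ref chars on the diagonal whose
# 1-based ref offset of read base 1 is `o`
oracle_diag_pref <- function(rdv, refv, o) {
  n <- length(rdv)
  idx <- o + seq_len(n) - 1
  ok <- idx >= 1 & idx <= length(refv)
  m <- logical(n)
  m[ok] <- rdv[ok] == refv[idx[ok]] & rdv[ok] %in% c("A", "C", "G", "T")
  c(0, cumsum(m))  # pref[i+1] = matches among first i read bases
}

# best admissible alignment of rd (strand applied) vs ref over the given
# seeded offsets; returns NULL or list(score, identity, gap_len)
oracle_best_alignment <- function(rd, ref, offsets, p) {
  rdv <- strsplit(rd, "", fixed = TRUE)[[1]]
  refv <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(rdv); L <- length(refv)
  best <- NULL
  consider <- function(m, pairs, cols, g) {
    identity <- 100 * m / cols
    if (identity + 1e-9 < p$min_identity) return()
    score <- p$match * m + p$mismatch * (pairs - m) -
      if (g > 0) p$gap_open + p$gap_extend * g else 0
    if (is.null(best) || score > best$score + 1e-9)
      best <<- list(score = score, identity = identity, gap_len = g)
  }
  for (o in offsets) {
    if (o >= 1 && o + n - 1 <= L)
      consider(oracle_diag_pref(rdv, refv, o)[n + 1], n, n, 0)
    for (g in seq_len(p$max_gap_len)) {
      # gap in the read row: right segment offset = left offset + g
      for (ol in unique(c(o, o - g))) {
        or <- ol + g
        if (ol < 1 || or + n - 1 > L) next
        prefL <- oracle_diag_pref(rdv, refv, ol)
        prefR <- oracle_diag_pref(rdv, refv, or)
        k <- seq_len(n - 1)
        m <- max(prefL[k + 1] + prefR[n + 1] - prefR[k + 1])
        consider(m, n, n + g, g)
      }
      # gap in the reference row: right segment offset = left offset - g
      if (n - g - 1 < 1) next
      for (or in unique(c(o - g, o))) {
        ol <- or + g
        if (or < 1 || or + n - 1 > L) next
        prefL <- oracle_diag_pref(rdv, refv, ol)
        prefR <- oracle_diag_pref(rdv, refv, or)
        k <- seq_len(n - g - 1)
        m <- max(prefL[k + 1] + prefR[n + 1] - prefR[k + g + 1])
        consider(m, n - g, n, g)
      }
    }
  }
  best
}

# full oracle: retained assignments for every read; returns tibble
# (read_id, cds_id, score, strand)
oracle_map_reads <- function(reads, reference, p = map_params()) {
  w <- p$word_size
  ref_kmers <- lapply(reference$sequence, oracle_kmer_positions, w = w)
  rows <- list()
  for (r in seq_len(nrow(reads))) {
    rd_fwd <- reads$sequence[r]
    if (nchar(rd_fwd) < w) next
    per_cds <- list()
    for (strand in c("+", "-")) {
      rd <- if (strand == "+") rd_fwd else oracle_revcomp(rd_fwd)
      rk <- oracle_kmer_positions(rd, w)
      for (ci in seq_len(nrow(reference))) {
        hit <- merge(rk, ref_kmers[[ci]], by = "kmer",
                     suffixes = c("_read", "_ref"))
        if (nrow(hit) == 0) next
        offsets <- sort(unique(hit$pos_ref - hit$pos_read + 1))
        b <- oracle_best_alignment(rd, reference$sequence[ci], offsets, p)
        if (is.null(b)) next
        key <- as.character(ci)
        if (is.null(per_cds[[key]]) || b$score > per_cds[[key]]$score + 1e-9)
          per_cds[[key]] <- c(b, strand = strand, ci = ci)
      }
    }
    if (length(per_cds) == 0) next
    scores <- vapply(per_cds, function(x) x$score, numeric(1))
    top <- max(scores)
    tied <- per_cds[scores > top - 1e-9]
    ids <- reference$cds_id[vapply(tied, function(x) x$ci, numeric(1))]
    ord <- order(ids)
    keep <- ord[seq_len(min(length(ord), p$max_hits))]
    for (j in keep) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        read_id = reads$read_id[r], cds_id = ids[j],
        score = tied[[j]]$score, strand = tied[[j]]$strand)
    }
  }
  if (length(rows) == 0)
    return(tibble::tibble(read_id = character(), cds_id = character(),
                          score = numeric(), strand = character()))
  dplyr::bind_rows(rows)
}
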