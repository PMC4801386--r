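# shared fixture builders (all deterministic under the caller's seed)

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_reference <- function(n_cds, len_range = c(150, 400), prefix = "CDS") {
  lens <- sample(seq(len_range[1], len_range[2]), n_cds, replace = TRUE)
  tibble::tibble(
    cds_id = sprintf("%s%03d", prefix, seq_len(n_cds)),
    sequence = vapply(lens, random_seq, character(1)),
    length = as.integer(lens))
}

# read drawn from a CDS with chosen substitutions (1-based positions within
# the read); subs replace the base by the next one in A->C->G->T->A order
make_read <- function(cds_seq, start, len, subs = integer(0)) {
  s <- substr(cds_seq, start, start + len - 1)
  for (p in subs) {
    old <- substr(s, p, p)
    new <- c(A = "C", C = "G", G = "T", T = "A")[[old]]
    substr(s, p, p) <- new
  }
  s
}

read_tbl <- function(seqs, ids = sprintf("read%03d", seq_along(seqs)),
                     quality = NULL, library_label = NULL) {
  out <- tibble::tibble(read_id = ids, sequence = seqs)
  out$quality <- if (is.null(quality))
    strrep(rawToChar(as.raw(33 + 35)), nchar(seqs)) else quality
  if (!is.null(library_label)) out$library_label <- library_label
  out
}

qual_string <- function(phreds) {
  rawToChar(as.raw(33 + phreds))
}
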