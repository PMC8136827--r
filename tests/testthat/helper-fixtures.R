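# Shared small fixtures, built in code at test time.

# A 60-nt locus cut at the midpoint with unique 10-mers, for hand-checkable
# dictionary arithmetic.
small_locus <- function(seed = 11) {
  make_locus(seed = seed, flank_len = 30, kmer_size = 10)
}

# Random junction spec that fits a locus, without engineered microhomology.
random_spec <- function(locus, max_del = 40, p_ins = 0.3) {
  if (stats::runif(1) < p_ins) {
    ins_len <- sample(1:12, 1)
    ins <- paste(sample(c("A", "C", "G", "T"), ins_len, replace = TRUE),
                 collapse = "")
  } else {
    ins <- ""
  }
  lim_l <- min(max_del, locus$cut_index - locus$kmer_size)
  lim_r <- min(max_del, nchar(locus$sequence) - locus$cut_index -
                 locus$kmer_size)
  tibble::tibble(
    left_del = sample(0:lim_l, 1),
    right_del = sample(0:lim_r, 1),
    mh_len = 0L,
    ins_seq = ins
  )
}

# Error-free paired reads from a template, for merge round-trips.
perfect_pair <- function(template, read_len, id = "p1") {
  n <- nchar(template)
  tibble::tibble(
    read_id = id,
    seq1 = substring(template, 1, min(read_len, n)),
    qual1 = strrep("I", min(read_len, n)),
    seq2 = reverse_complement(substring(template, max(1, n - read_len + 1), n)),
    qual2 = strrep("I", min(read_len, n))
  )
}

# Hand-built scar-call tibbles for tabulation tests.
make_calls <- function(n, left = 0L, right = 0L, mh = "", ins = "",
                       status = "SCAR") {
  tibble::tibble(
    read_id = sprintf("r%03d", seq_len(n)), status = status,
    left_del = left, right_del = right, mh_seq = mh, ins_seq = ins,
    total_del = left + right + nchar(mh)
  )
}
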