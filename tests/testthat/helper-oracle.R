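# Independent brute-force oracles. These deliberately avoid the package's
# regex-based matching: every occurrence test is a naive position-by-position
# substring comparison, and the merge oracle scores every offset.

# All 0-based start positions of `kmer` in `x`, by naive comparison.
naive_occurrences <- function(x, kmer) {
  k <- nchar(kmer)
  n <- nchar(x)
  if (n < k) return(integer(0))
  starts <- 0:(n - k)
  starts[vapply(starts, function(s) {
    substring(x, s + 1, s + k) == kmer
  }, logical(1))]
}

# Smallest deletion whose flank k-mer occurs in the read, enumerating every
# (deletion, occurrence) pair; same occurrence tie-breaks as the contract
# (upstream: rightmost with room for a downstream anchor start; downstream:
# leftmost at or after search_from).
oracle_flank <- function(consensus, dict, search_from = 0) {
  k <- attr(dict, "kmer_size")
  upstream <- identical(attr(dict, "side"), "upstream")
  len <- nchar(consensus)
  for (i in seq_len(nrow(dict))) {
    occ <- naive_occurrences(consensus, dict$kmer[i])
    occ <- occ[occ >= search_from]
    if (upstream) occ <- occ[occ + k - 1 <= len - 2]
    if (length(occ) > 0) {
      s <- if (upstream) max(occ) else min(occ)
      return(list(deletion = dict$deletion[i], match_start = s,
                  match_end = s + k - 1, found = TRUE))
    }
  }
  list(found = FALSE)
}

# Full canonical decomposition of an error-free read via the brute-force
# flank scans; the reference point for round-trip and minimality checks.
oracle_decompose <- function(consensus, locus) {
  dicts <- build_flank_dictionaries(locus)
  k <- locus$kmer_size
  uf <- oracle_flank(consensus, dicts$upstream)
  if (!uf$found) return(list(status = "UNRESOLVED"))
  df <- oracle_flank(consensus, dicts$downstream,
                     search_from = uf$match_end - k + 2)
  if (!df$found) return(list(status = "UNRESOLVED"))
  p_u <- uf$match_end
  p_d <- df$match_start
  if (p_d == p_u + 1 && uf$deletion == 0 && df$deletion == 0) {
    return(list(status = "NO_SCAR", left_del = 0L, right_del = 0L,
                mh_seq = "", ins_seq = "", total_del = 0L))
  }
  mh <- if (p_d <= p_u) substring(consensus, p_d + 1, p_u + 1) else ""
  ins <- if (p_d > p_u + 1) substring(consensus, p_u + 2, p_d) else ""
  list(status = "SCAR", left_del = uf$deletion, right_del = df$deletion,
       mh_seq = mh, ins_seq = ins,
       total_del = uf$deletion + df$deletion + nchar(mh))
}

# Reconstruction check: splice the called scar back into the reference and
# verify the consensus is a substring of the reconstructed amplicon.
oracle_reconstructs <- function(consensus, locus, call) {
  cut <- locus$cut_index
  len <- nchar(locus$sequence)
  rebuilt <- paste0(
    substring(locus$sequence, 1, cut - call$left_del),
    call$ins_seq,
    substring(locus$sequence,
              cut + call$right_del + nchar(call$mh_seq) + 1, len)
  )
  grepl(consensus, rebuilt, fixed = TRUE)
}

# Exhaustive ungapped overlap scorer for pair merging: every offset of the
# reverse-complemented mate against read 1, scored by match count.
oracle_best_offset <- function(seq1, seq2, min_overlap, max_mismatch_frac) {
  s2 <- reverse_complement(seq2)
  c1 <- strsplit(seq1, "")[[1]]
  c2 <- strsplit(s2, "")[[1]]
  n1 <- length(c1)
  n2 <- length(c2)
  best <- NULL
  for (o in seq(-(n2 - 1), n1 - 1)) {
    a <- max(1, o + 1)
    b <- min(n1, o + n2)
    len <- b - a + 1
    if (len < min_overlap) next
    matches <- sum(c1[a:b] == c2[(a - o):(b - o)])
    if ((len - matches) / len > max_mismatch_frac) next
    if (is.null(best) || matches > best$matches ||
        (matches == best$matches && len > best$len)) {
      best <- list(matches = matches, len = len, offset = o)
    }
  }
  best
}
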