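#' Read paired-end FASTQ files into a tibble of read pairs
#'
#' Mates are matched positionally (lockstep order), as produced by standard
#' demultiplexers. Gzip-compressed input is handled transparently.
#' Qualities are kept as Sanger Phred+33 strings.
#'
#' @param path1,path2 Paths to the read-1 and read-2 FASTQ files (optionally
#'   `.gz`).
#' @return A tibble with columns `read_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  for (p in c(path1, path2)) {
    if (!file.exists(p)) stop("FASTQ file not found: ", p, call. = FALSE)
  }
  read_fq <- function(p) {
    # Biostrings warns about dropping FASTQ metadata columns we never use
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(p),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  r1 <- read_fq(path1)
  r2 <- read_fq(path2)
  if (length(r1) != length(r2)) {
    stop("mate-count mismatch: record ", min(length(r1), length(r2)) + 1L,
         " present in only one file (", length(r1), " vs ", length(r2),
         " records)", call. = FALSE)
  }
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(r1)),
    seq1 = as.character(r1),
    qual1 = as.character(Biostrings::quality(r1)),
    seq2 = as.character(r2),
    qual2 = as.character(Biostrings::quality(r2))
  )
}

#' Write a tibble of read pairs as paired FASTQ
#'
#' @param pairs Tibble as returned by [read_fastq_pairs()] or
#'   [simulate_scar_library()].
#' @param path1,path2 Output paths; a `.gz` suffix triggers gzip compression.
#' @return Invisibly, `c(path1, path2)`.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  stopifnot(all(c("read_id", "seq1", "qual1", "seq2", "qual2") %in% names(pairs)))
  write_one <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(quals),
      compress = grepl("\\.gz$", path)
    )
  }
  write_one(pairs$seq1, pairs$qual1, pairs$read_id, path1)
  write_one(pairs$seq2, pairs$qual2, pairs$read_id, path2)
  invisible(c(path1, path2))
}

phred_ints <- function(qual) utf8ToInt(qual) - 33L
phred_string <- function(ints) intToUtf8(ints + 33L)

validate_mate <- function(seq, qual, what) {
  if (nchar(seq) == 0L) stop("empty ", what, call. = FALSE)
  if (nchar(seq) != nchar(qual)) {
    stop("length mismatch between seq and qual for ", what, call. = FALSE)
  }
  q <- phred_ints(qual)
  if (any(q < 0L | q > 93L)) {
    stop("Phred scores out of range 0-93 for ", what, call. = FALSE)
  }
  invisible(q)
}

# Exact-seed candidate offsets for the overlap search: occurrences of short
# prefix seeds of either read inside the other pin down the likely relative
# offsets, so only those need scoring. Substitution errors inside a seed are
# caught by the exhaustive fallback in merge_one_pair.
candidate_offsets <- function(s1, s2, n1, n2, seed_len = 15L) {
  offs <- integer(0)
  for (sp in c(1L, seed_len + 1L)) {
    if (sp + seed_len - 1L <= n2) {
      starts <- kmer_occurrences(s1, substr(s2, sp, sp + seed_len - 1L))
      offs <- c(offs, starts - (sp - 1L))
    }
  }
  if (n1 >= seed_len) {
    starts <- kmer_occurrences(s2, substr(s1, 1L, seed_len))
    offs <- c(offs, -starts)
  }
  sort(unique(offs))
}

# Ungapped overlap merge of one pair. Read 2 is reverse-complemented and the
# highest-identity qualifying offset (overlap >= min_overlap, mismatch
# fraction <= max_mismatch_frac) defines the consensus; seed-derived
# candidate offsets are scored first and all offsets only when no candidate
# qualifies. Disagreements in the overlap take the higher-Phred base (ties:
# read-1 base, minimum quality).
merge_one_pair <- function(seq1, qual1, seq2, qual2, min_overlap,
                           max_mismatch_frac) {
  q1 <- validate_mate(seq1, qual1, "read 1")
  q2 <- validate_mate(seq2, qual2, "read 2")
  s2 <- reverse_complement(seq2)
  q2 <- rev(q2)
  r1 <- charToRaw(seq1)
  r2 <- charToRaw(s2)
  n1 <- length(r1)
  n2 <- length(r2)
  score_offsets <- function(offsets) {
    best <- NULL
    for (o in offsets) {
      a <- max(1L, o + 1L)           # 1-based overlap bounds on read 1
      b <- min(n1, o + n2)
      len <- b - a + 1L
      if (len < min_overlap) next
      matches <- sum(r1[a:b] == r2[(a - o):(b - o)])
      if ((len - matches) / len > max_mismatch_frac) next
      if (is.null(best) ||
          matches > best[["matches"]] ||
          (matches == best[["matches"]] && len > best[["len"]])) {
        best <- c(matches = matches, len = len, o = o)
      }
    }
    best
  }
  best <- score_offsets(candidate_offsets(seq1, s2, n1, n2))
  if (is.null(best)) {
    all_offsets <- seq.int(max(-(n2 - min_overlap), -(n2 - 1L)),
                           min(n1 - min_overlap, n1 - 1L))
    best <- score_offsets(all_offsets)
  }
  if (is.null(best)) {
    return(list(merged = FALSE, seq = NA_character_, qual = NA_character_))
  }
  o <- best[["o"]]
  lo <- min(1L, o + 1L)
  hi <- max(n1, o + n2)
  pos <- lo:hi
  base <- raw(length(pos))
  qual <- integer(length(pos))
  in1 <- pos >= 1L & pos <= n1
  in2 <- pos >= o + 1L & pos <= o + n2
  base[in1] <- r1[pos[in1]]
  qual[in1] <- q1[pos[in1]]
  only2 <- in2 & !in1
  base[only2] <- r2[pos[only2] - o]
  qual[only2] <- q2[pos[only2] - o]
  both <- in1 & in2
  if (any(both)) {
    p1 <- pos[both]
    b1 <- r1[p1]; b2 <- r2[p1 - o]
    qq1 <- q1[p1]; qq2 <- q2[p1 - o]
    agree <- b1 == b2
    out_b <- b1
    out_q <- pmax(qq1, qq2)
    dis <- !agree
    take2 <- dis & qq2 > qq1
    out_b[take2] <- b2[take2]
    out_q[take2] <- qq2[take2]
    take1 <- dis & qq1 > qq2
    out_q[take1] <- qq1[take1]
    tie <- dis & qq1 == qq2
    out_q[tie] <- pmin(qq1, qq2)[tie]   # read-1 base already in out_b
    base[both] <- out_b
    qual[both] <- out_q
  }
  list(merged = TRUE, seq = rawToChar(base), qual = phred_string(qual))
}

#' Merge read pairs into consensus reads
#'
#' Read 2 is reverse-complemented and the highest-scoring ungapped overlap
#' of length at least `min_overlap` with mismatch fraction at most
#' `max_mismatch_frac` defines the consensus. Within the overlap,
#' disagreeing positions take the base with the higher Phred score (ties go
#' to read 1 with the minimum of the two qualities); outside the overlap
#' bases come from the covering mate. Pairs with no qualifying overlap are
#' returned with `merged = FALSE` and are excluded from junction calling.
#'
#' @param pairs Tibble with columns `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @param min_overlap Minimum overlap length in nt (default 20, the width of
#'   the two flank k-mers that define a junction).
#' @param max_mismatch_frac Maximum mismatch fraction tolerated in the
#'   overlap (default 0.1).
#' @return A tibble with columns `read_id`, `merged`, `seq`, `qual`.
#' @export
merge_pairs <- function(pairs, min_overlap = 20L, max_mismatch_frac = 0.1) {
  stopifnot(all(c("read_id", "seq1", "qual1", "seq2", "qual2") %in% names(pairs)))
  res <- purrr::pmap(
    list(pairs$seq1, pairs$qual1, pairs$seq2, pairs$qual2),
    merge_one_pair,
    min_overlap = as.integer(min_overlap),
    max_mismatch_frac = max_mismatch_frac
  )
  tibble::tibble(
    read_id = pairs$read_id,
    merged = purrr::map_lgl(res, "merged"),
    seq = purrr::map_chr(res, "seq"),
    qual = purrr::map_chr(res, "qual")
  )
}
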