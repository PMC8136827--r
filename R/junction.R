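#' Locate a flank k-mer in a consensus read
#'
#' Scans a flank dictionary in order of increasing deletion size and returns
#' the smallest deletion whose k-mer occurs in the read, together with the
#' chosen occurrence. The upstream flank takes the rightmost qualifying
#' occurrence (leaving at least one base after it so a downstream anchor can
#' start); the downstream flank takes the leftmost occurrence starting at or
#' after `search_from`. Both choices bias the anchors toward the junction,
#' consistent with least-deletion semantics.
#'
#' Positions are 0-based read coordinates.
#'
#' @param consensus A single consensus read sequence.
#' @param dict One element of [build_flank_dictionaries()] output.
#' @param search_from Smallest allowed 0-based start position of the match
#'   (used for the downstream search; 0 for upstream).
#' @return A list with `deletion`, `match_start`, `match_end` (0-based,
#'   inclusive) and `found`; `found = FALSE` when no dictionary entry
#'   matches.
#' @export
find_flank <- function(consensus, dict, search_from = 0L) {
  stopifnot(is.character(consensus), length(consensus) == 1L)
  side <- attr(dict, "side")
  k <- attr(dict, "kmer_size")
  len <- nchar(consensus)
  upstream <- identical(side, "upstream")
  for (i in seq_len(nrow(dict))) {
    starts <- kmer_occurrences(consensus, dict$kmer[i])  # 0-based starts
    starts <- starts[starts >= search_from]
    if (upstream) {
      # keep room for a downstream anchor start after the flank end
      starts <- starts[starts + k - 1L <= len - 2L]
    }
    if (length(starts) == 0L) next
    s <- if (upstream) max(starts) else min(starts)
    return(list(deletion = dict$deletion[i], match_start = s,
                match_end = s + k - 1L, found = TRUE))
  }
  list(deletion = NA_integer_, match_start = NA_integer_,
       match_end = NA_integer_, found = FALSE)
}

# All 0-based start positions of fixed pattern `kmer` in `x`.
kmer_occurrences <- function(x, kmer) {
  m <- gregexpr(kmer, x, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

# Decompose one consensus read against a locus. Returns a one-row list.
call_one_junction <- function(consensus, locus, dicts) {
  k <- locus$kmer_size
  if (!is.null(locus$donor_marker) &&
      grepl(locus$donor_marker, consensus, fixed = TRUE)) {
    return(scar_row("HR", 0L, 0L, "", ""))
  }
  if (is.na(consensus) || nchar(consensus) < 2L * k) {
    return(scar_row("UNRESOLVED", reason = "too short"))
  }
  uf <- find_flank(consensus, dicts$upstream, search_from = 0L)
  if (!uf$found) return(scar_row("UNRESOLVED", reason = "no upstream flank"))
  p_u <- uf$match_end
  df <- find_flank(consensus, dicts$downstream, search_from = p_u - k + 2L)
  if (!df$found) return(scar_row("UNRESOLVED", reason = "no downstream flank"))
  p_d <- df$match_start
  d_u <- uf$deletion
  d_d <- df$deletion
  if (p_d == p_u + 1L && d_u == 0L && d_d == 0L) {
    return(scar_row("NO_SCAR", 0L, 0L, "", ""))
  }
  if (p_d <= p_u) {
    # overlapping anchors: the read-coordinate overlap is the microhomology;
    # each flank search retained its own MH copy, so d_u and d_d are already
    # MH-exclusive and total_del = d_u + d_d + |mh|
    mh <- stringr::str_sub(consensus, p_d + 1L, p_u + 1L)
    return(scar_row("SCAR", d_u, d_d, mh, ""))
  }
  ins <- if (p_d > p_u + 1L) {
    stringr::str_sub(consensus, p_u + 2L, p_d)
  } else ""
  scar_row("SCAR", d_u, d_d, "", ins)
}

scar_row <- function(status, left_del = NA_integer_, right_del = NA_integer_,
                     mh_seq = NA_character_, ins_seq = NA_character_,
                     reason = NA_character_) {
  left_del <- as.integer(left_del)
  right_del <- as.integer(right_del)
  total <- if (is.na(left_del)) NA_integer_ else {
    left_del + right_del + nchar(mh_seq)
  }
  list(status = status, left_del = left_del, right_del = right_del,
       mh_seq = mh_seq, ins_seq = ins_seq, total_del = total, reason = reason)
}

#' Call repair-scar junctions on consensus reads
#'
#' The break-anchored decomposition: for each read, the upstream flank (UF)
#' is the dictionary k-mer with the least upstream deletion that matches the
#' read, then the downstream flank (DF) is the k-mer with the least
#' downstream deletion matching at or after `p_u - k + 2` (so anchor
#' overlaps up to k - 1 are visible). Perfectly abutted anchors with zero
#' deletion are unedited reads (`NO_SCAR`); abutted or separated anchors
#' with deletion describe simple deletions; overlapping anchors describe a
#' microhomology-associated deletion (the overlap is the microhomology);
#' sequence between the anchors is an insertion. Reads containing the donor
#' gene-conversion marker are called `HR` before any anchor search. Reads
#' where either flank cannot be located are `UNRESOLVED` and excluded from
#' frequency denominators.
#'
#' The total deletion size is the sum of the left deletion, right deletion
#' and microhomology length.
#'
#' @param reads Tibble with columns `read_id` and `seq` (e.g. the merged
#'   rows of [merge_pairs()] output), or a character vector of sequences.
#' @param locus A [target_locus()].
#' @return A tibble with columns `read_id`, `status` (one of SCAR, HR,
#'   NO_SCAR, UNRESOLVED), `left_del`, `right_del`, `mh_seq`, `ins_seq`,
#'   `total_del`, `reason`.
#' @examples
#' fx <- signature_fixtures()
#' call_junctions(fx$tmej23$consensus, fx$tmej23$locus)
#' @export
call_junctions <- function(reads, locus) {
  stopifnot(inherits(locus, "target_locus"))
  if (is.character(reads)) {
    reads <- tibble::tibble(
      read_id = paste0("read", seq_along(reads)), seq = reads
    )
  }
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  if ("merged" %in% names(reads)) {
    reads <- dplyr::filter(reads, .data$merged)
  }
  if (nrow(reads) == 0L) {
    return(tibble::tibble(
      read_id = character(), status = character(), left_del = integer(),
      right_del = integer(), mh_seq = character(), ins_seq = character(),
      total_del = integer(), reason = character()
    ))
  }
  dicts <- build_flank_dictionaries(locus)
  rows <- purrr::map(reads$seq, call_one_junction, locus = locus,
                     dicts = dicts)
  dplyr::bind_cols(
    tibble::tibble(read_id = reads$read_id),
    dplyr::bind_rows(purrr::map(rows, tibble::as_tibble))
  )
}
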