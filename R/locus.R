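#' Describe a Cas9-targeted amplicon locus
#'
#' A target locus bundles the reference amplicon sequence (5'->3' on the
#' sequenced strand), the blunt Cas9 cut position, the flank k-mer window
#' size, and an optional donor gene-conversion marker used to detect
#' homologous recombination. All junction arithmetic downstream is anchored
#' to this object.
#'
#' Coordinates are 0-based and half-open: `cut_index` counts reference bases
#' 5' of the blunt cut, so the cut lies between positions `cut_index - 1`
#' and `cut_index`.
#'
#' @param sequence Reference amplicon, a single string over A/C/G/T.
#' @param cut_index Integer, number of reference bases 5' of the blunt cut
#'   (0-based, half-open).
#' @param name Text label for the locus.
#' @param kmer_size Flank window size in nt; default 10, minimum 6 (smaller
#'   windows give spurious matches).
#' @param donor_marker Optional donor-specific gene-conversion sequence
#'   (recommended length >= 12); its presence in a consensus read marks the
#'   read as an HR product.
#' @return An object of class `target_locus`.
#' @examples
#' loc <- target_locus(strrep("ACGT", 15), cut_index = 30)
#' loc
#' @export
target_locus <- function(sequence, cut_index, name = "locus", kmer_size = 10L,
                         donor_marker = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stop("reference sequence must contain only A/C/G/T", call. = FALSE)
  }
  cut_index <- as.integer(cut_index)
  kmer_size <- as.integer(kmer_size)
  len <- nchar(sequence)
  if (kmer_size < 6L) {
    stop("kmer_size must be >= 6", call. = FALSE)
  }
  if (cut_index < kmer_size) {
    stop("upstream flank shorter than kmer_size: cut_index = ", cut_index,
         ", kmer_size = ", kmer_size, call. = FALSE)
  }
  if (len - cut_index < kmer_size) {
    stop("downstream flank shorter than kmer_size: ", len - cut_index,
         " nt available, kmer_size = ", kmer_size, call. = FALSE)
  }
  if (!is.null(donor_marker)) {
    donor_marker <- toupper(donor_marker)
    stopifnot(is.character(donor_marker), length(donor_marker) == 1L)
    if (grepl("[^ACGT]", donor_marker)) {
      stop("donor_marker must contain only A/C/G/T", call. = FALSE)
    }
  }
  structure(
    list(name = name, sequence = sequence, cut_index = cut_index,
         kmer_size = kmer_size, donor_marker = donor_marker),
    class = "target_locus"
  )
}

#' @export
print.target_locus <- function(x, ...) {
  cat("<target_locus> ", x$name, "\n", sep = "")
  cat("  amplicon: ", nchar(x$sequence), " nt, cut after base ", x$cut_index,
      " (0-based)\n", sep = "")
  cat("  kmer_size: ", x$kmer_size, "\n", sep = "")
  if (!is.null(x$donor_marker)) {
    cat("  donor marker: ", x$donor_marker, "\n", sep = "")
  }
  invisible(x)
}

#' Read a target locus from a single-record FASTA file
#'
#' @param fasta Path to a single-record FASTA file holding the reference
#'   amplicon.
#' @inheritParams target_locus
#' @return A `target_locus`.
#' @export
read_target_locus <- function(fasta, cut_index, kmer_size = 10L,
                              donor_marker = NULL, name = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) {
    stop("expected a single-record FASTA, found ", length(seqs), " records in ",
         fasta, call. = FALSE)
  }
  target_locus(as.character(seqs[[1L]]), cut_index = cut_index,
               name = name %||% names(seqs)[1L], kmer_size = kmer_size,
               donor_marker = donor_marker)
}

#' Build the upstream/downstream flank k-mer dictionaries for a locus
#'
#' For every deletion size d (in 1-nt increments) the upstream dictionary
#' holds the k-mer of reference sequence ending d bases 5' of the cut, and
#' the downstream dictionary the k-mer starting d bases 3' of the cut. The
#' d = 0 entries abut the cut. These dictionaries anchor the junction
#' decomposition: the flank with the least deletion that still matches the
#' read defines each side of the junction.
#'
#' @param locus A [target_locus()].
#' @return A list with elements `upstream` and `downstream`, each a tibble
#'   with columns `deletion` and `kmer` and attributes `side`,
#'   `max_deletion`, `kmer_size`.
#' @examples
#' loc <- make_locus(seed = 1, flank_len = 30)
#' d <- build_flank_dictionaries(loc)
#' head(d$upstream)
#' @export
build_flank_dictionaries <- function(locus) {
  stopifnot(inherits(locus, "target_locus"))
  k <- locus$kmer_size
  cut <- locus$cut_index
  len <- nchar(locus$sequence)
  up_max <- cut - k
  dn_max <- len - cut - k
  up_d <- 0:up_max
  dn_d <- 0:dn_max
  # 1-based substring windows; upstream entry d spans [cut-d-k, cut-d) 0-based
  up <- tibble::tibble(
    deletion = up_d,
    kmer = stringr::str_sub(locus$sequence, cut - up_d - k + 1L, cut - up_d)
  )
  dn <- tibble::tibble(
    deletion = dn_d,
    kmer = stringr::str_sub(locus$sequence, cut + dn_d + 1L, cut + dn_d + k)
  )
  attr(up, "side") <- "upstream"
  attr(dn, "side") <- "downstream"
  attr(up, "max_deletion") <- up_max
  attr(dn, "max_deletion") <- dn_max
  attr(up, "kmer_size") <- k
  attr(dn, "kmer_size") <- k
  list(upstream = up, downstream = dn)
}

#' Reverse-complement DNA sequences
#'
#' Vectorised Watson-Crick reverse complement over A/C/G/T/N.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement(c("ACGT", "AAAC"))
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  bad <- grepl("[^ACGTNacgtn]", seq)
  if (any(bad)) {
    stop("non-IUPAC character in sequence(s): ",
         paste(utils::head(which(bad), 3L), collapse = ", "), call. = FALSE)
  }
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(toupper(seq))
  ))
  unname(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
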