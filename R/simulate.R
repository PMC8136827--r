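random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

all_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# Preserve the caller's RNG state while running seeded code.
with_seed_local <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a random target locus with unique k-mers
#'
#' Rejection-samples a random amplicon in which every k-mer occurs exactly
#' once, cut at the midpoint. Unique k-mers make flank matches unambiguous,
#' so simulated scars have a single correct decomposition.
#'
#' @param seed Integer seed (reproducible; the caller's RNG state is
#'   preserved). `NULL` uses the current RNG state.
#' @param flank_len Length of each flank; the amplicon is `2 * flank_len`
#'   nt. Default 240 (a ~480 nt amplicon, the scale of a typical sequenced
#'   Cas9 target region).
#' @param kmer_size Flank window size (default 10).
#' @param max_tries Rejection-sampling budget.
#' @return A `target_locus` cut at the midpoint.
#' @export
make_locus <- function(seed = NULL, flank_len = 240L, kmer_size = 10L,
                       max_tries = 200L) {
  flank_len <- as.integer(flank_len)
  if (flank_len < kmer_size + 10L) {
    stop("flank_len must be >= kmer_size + 10", call. = FALSE)
  }
  with_seed_local(seed, {
    for (i in seq_len(max_tries)) {
      seq <- random_dna(2L * flank_len)
      if (anyDuplicated(all_kmers(seq, kmer_size)) == 0L) {
        return(target_locus(seq, cut_index = flank_len,
                            name = sprintf("sim_locus_%dnt", 2L * flank_len),
                            kmer_size = kmer_size))
      }
    }
    stop("could not generate a unique-k-mer amplicon in ", max_tries,
         " tries; increase kmer_size or shorten the amplicon", call. = FALSE)
  })
}

validate_mh_reference <- function(sequence, motif, kmer_size) {
  n_occ <- length(kmer_occurrences(sequence, motif))
  if (n_occ != 2L) {
    stop("microhomology motif must occur exactly twice in the reference ",
         "(found ", n_occ, " occurrences)", call. = FALSE)
  }
  if (anyDuplicated(all_kmers(sequence, kmer_size)) != 0L) {
    stop("reference k-mers are not unique", call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate a locus carrying an engineered microhomology pair
#'
#' Constructs a reference of the form upstream anchor + motif + left
#' segment + right segment + motif + downstream anchor, with the cut
#' between the left and right segments. The motif occurs exactly twice and
#' every k-mer is unique, so a deletion spanning both gap segments and one
#' motif copy is a microhomology-mediated junction with a single correct
#' decomposition: left deletion `left_gap`, right deletion `right_gap`,
#' microhomology `motif_len`.
#'
#' @param seed Integer seed (see [make_locus()]).
#' @param motif_len Microhomology motif length in nt (must be smaller than
#'   `kmer_size`).
#' @param left_gap,right_gap Lengths of the segments between the motif
#'   copies, 5' and 3' of the cut.
#' @param anchor_len Anchor lengths; length-2 vector (upstream, downstream)
#'   or a single value used for both.
#' @param kmer_size Flank window size (default 10).
#' @param max_tries Rejection-sampling budget.
#' @return A `target_locus` with extra fields `motif` and `mh_truth` (the
#'   spec of the engineered junction).
#' @examples
#' loc <- make_mh_locus(seed = 1, motif_len = 6, left_gap = 9,
#'                      right_gap = 8, anchor_len = c(15, 16))
#' loc$mh_truth
#' @export
make_mh_locus <- function(seed = NULL, motif_len, left_gap, right_gap,
                          anchor_len, kmer_size = 10L, max_tries = 200L) {
  stopifnot(motif_len > 0L, left_gap > 0L, right_gap > 0L,
            all(anchor_len > 0L))
  if (motif_len >= kmer_size) {
    stop("motif_len must be smaller than kmer_size to keep k-mers unique",
         call. = FALSE)
  }
  anchor_len <- rep_len(as.integer(anchor_len), 2L)
  if (any(anchor_len + motif_len < kmer_size)) {
    stop("anchors too short: anchor_len + motif_len must be >= kmer_size",
         call. = FALSE)
  }
  cut <- anchor_len[1L] + motif_len + left_gap
  with_seed_local(seed, {
    for (i in seq_len(max_tries)) {
      motif <- random_dna(motif_len)
      a_up <- random_dna(anchor_len[1L])
      l_seg <- random_dna(left_gap)
      r_seg <- random_dna(right_gap)
      a_dn <- random_dna(anchor_len[2L])
      # the engineered microhomology must not extend by chance: the base
      # after each motif copy and the base before each copy must differ
      # between the two junction sides, or the overlap grows past motif_len
      if (substr(l_seg, 1L, 1L) == substr(a_dn, 1L, 1L)) next
      if (substr(r_seg, right_gap, right_gap) ==
            substr(a_up, anchor_len[1L], anchor_len[1L])) next
      seq <- paste0(a_up, motif, l_seg, r_seg, motif, a_dn)
      ok <- tryCatch({
        validate_mh_reference(seq, motif, kmer_size)
        TRUE
      }, error = function(e) FALSE)
      if (ok) {
        loc <- target_locus(seq, cut_index = cut,
                            name = sprintf("sim_mh_locus_%dbpMH", motif_len),
                            kmer_size = kmer_size)
        loc$motif <- motif
        loc$mh_truth <- tibble::tibble(
          left_del = as.integer(left_gap), right_del = as.integer(right_gap),
          mh_len = as.integer(motif_len), ins_seq = ""
        )
        return(loc)
      }
    }
    stop("could not generate a valid microhomology locus in ", max_tries,
         " tries", call. = FALSE)
  })
}

#' Apply a repair scar to a reference amplicon
#'
#' Deletes `left_del + mh_len + right_del` reference bases spanning the cut
#' (retaining one copy of the microhomology at the junction) and splices in
#' `ins_seq`. For `mh_len > 0` the reference must carry the repeat pair:
#' the `mh_len` bases immediately 5' of the deleted left segment must equal
#' the `mh_len` bases immediately 3' of the deleted right segment.
#'
#' @param locus A `target_locus`.
#' @param left_del,right_del Deleted bases immediately 5'/3' of the cut,
#'   excluding the microhomology.
#' @param mh_len Microhomology length.
#' @param ins_seq Inserted sequence (possibly empty). A microhomology and
#'   an insertion are mutually exclusive.
#' @return The scarred amplicon sequence.
#' @export
apply_scar <- function(locus, left_del = 0L, right_del = 0L, mh_len = 0L,
                       ins_seq = "") {
  stopifnot(inherits(locus, "target_locus"))
  left_del <- as.integer(left_del); right_del <- as.integer(right_del)
  mh_len <- as.integer(mh_len)
  if (mh_len > 0L && nchar(ins_seq) > 0L) {
    stop("a junction cannot carry both a microhomology and an insertion",
         call. = FALSE)
  }
  cut <- locus$cut_index
  len <- nchar(locus$sequence)
  if (left_del < 0L || right_del < 0L || mh_len < 0L ||
      cut - left_del - mh_len < 0L || cut + right_del + mh_len > len) {
    stop("scar does not fit inside the amplicon", call. = FALSE)
  }
  if (mh_len > 0L) {
    up_copy <- stringr::str_sub(locus$sequence, cut - left_del - mh_len + 1L,
                                cut - left_del)
    dn_copy <- stringr::str_sub(locus$sequence, cut + right_del + 1L,
                                cut + right_del + mh_len)
    if (up_copy != dn_copy) {
      stop("reference does not carry the microhomology repeat pair for this ",
           "scar geometry", call. = FALSE)
    }
  }
  paste0(stringr::str_sub(locus$sequence, 1L, cut - left_del),
         ins_seq,
         stringr::str_sub(locus$sequence, cut + right_del + mh_len + 1L, len))
}

add_substitutions <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(chars)) < error_rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# Vectorised substitution errors: draw per-read error counts first so only
# reads that actually carry an error pay the string-splitting cost.
add_substitutions_vec <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    chars <- strsplit(seqs[i], "")[[1L]]
    pos <- sample.int(length(chars), n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

random_quals <- function(n) phred_string(sample(30:40, n, replace = TRUE))

#' Simulate one paired-end read from a scarred amplicon
#'
#' Applies the scar to the reference, prepends a random 0-8 nt phasing
#' prefix (emulating phased amplicon primers), and emits overlapping mates
#' of `read_len` with independent per-base substitution errors and
#' plausible Phred qualities.
#'
#' @param locus A `target_locus`.
#' @param spec One-row data frame or list with `left_del`, `right_del`,
#'   `mh_len`, `ins_seq`.
#' @param read_len Mate length in nt (default 300, paired 300-cycle
#'   chemistry).
#' @param error_rate Per-base substitution probability (default 0).
#' @param phasing_max Maximum phasing-prefix length (default 8).
#' @param read_id Read identifier.
#' @param seed Optional seed (see [make_locus()]).
#' @return One-row tibble: `read_id`, `seq1`, `qual1`, `seq2`, `qual2`,
#'   plus the truth columns of `spec`.
#' @export
make_read_pair <- function(locus, spec, read_len = 300L, error_rate = 0,
                           phasing_max = 8L, read_id = "sim_read",
                           seed = NULL) {
  with_seed_local(seed, {
    spec <- as.list(spec)
    scarred <- apply_scar(locus, spec$left_del, spec$right_del, spec$mh_len,
                          spec$ins_seq)
    phase <- sample(0:phasing_max, 1L)
    amp <- paste0(if (phase > 0L) random_dna(phase) else "", scarred)
    n <- nchar(amp)
    s1 <- stringr::str_sub(amp, 1L, min(read_len, n))
    s2 <- reverse_complement(stringr::str_sub(amp, max(1L, n - read_len + 1L), n))
    s1 <- add_substitutions(s1, error_rate)
    s2 <- add_substitutions(s2, error_rate)
    tibble::tibble(
      read_id = read_id,
      seq1 = s1, qual1 = random_quals(nchar(s1)),
      seq2 = s2, qual2 = random_quals(nchar(s2)),
      left_del = as.integer(spec$left_del),
      right_del = as.integer(spec$right_del),
      mh_len = as.integer(spec$mh_len), ins_seq = spec$ins_seq,
      phasing = phase
    )
  })
}

#' Simulate a scarred-read library from a mixture of repair products
#'
#' Draws each read's repair product from `mixture` (multinomial at the
#' given frequencies; frequencies below 1 are topped up with unedited
#' reads), then simulates paired-end reads with [make_read_pair()]. The
#' returned truth manifest records the drawn spec for every read.
#'
#' @param locus A `target_locus`.
#' @param mixture Tibble with columns `left_del`, `right_del`, `mh_len`,
#'   `ins_seq`, `frequency` (frequencies sum to at most 1; the remainder
#'   becomes unedited reads).
#' @param n_reads Number of read pairs.
#' @inheritParams make_read_pair
#' @param seed Integer seed for the whole library.
#' @return List with `pairs` (FASTQ-ready tibble) and `truth` (per-read
#'   manifest with the drawn spec).
#' @export
simulate_scar_library <- function(locus, mixture, n_reads, read_len = 300L,
                                  error_rate = 0.001, phasing_max = 8L,
                                  seed = NULL) {
  mixture <- tibble::as_tibble(mixture)
  stopifnot(all(c("left_del", "right_del", "mh_len", "ins_seq", "frequency")
                %in% names(mixture)))
  tot <- sum(mixture$frequency)
  if (tot > 1 + 1e-9) stop("mixture frequencies sum to more than 1", call. = FALSE)
  specs <- dplyr::select(mixture, "left_del", "right_del", "mh_len",
                         "ins_seq", "frequency")
  if (tot < 1) {
    specs <- dplyr::bind_rows(
      specs,
      tibble::tibble(left_del = 0L, right_del = 0L, mh_len = 0L,
                     ins_seq = "", frequency = 1 - tot)
    )
  }
  with_seed_local(seed, {
    draw <- sample.int(nrow(specs), n_reads, replace = TRUE,
                       prob = specs$frequency)
    scarred <- vapply(seq_len(nrow(specs)), function(i) {
      apply_scar(locus, specs$left_del[i], specs$right_del[i],
                 specs$mh_len[i], specs$ins_seq[i])
    }, character(1))
    phase <- sample.int(phasing_max + 1L, n_reads, replace = TRUE) - 1L
    prefix <- vapply(phase, function(p) {
      if (p > 0L) random_dna(p) else ""
    }, character(1))
    amp <- paste0(prefix, scarred[draw])
    n <- nchar(amp)
    s1 <- stringr::str_sub(amp, 1L, pmin(read_len, n))
    s2 <- reverse_complement(stringr::str_sub(amp, pmax(1L, n - read_len + 1L), n))
    s1 <- add_substitutions_vec(s1, error_rate)
    s2 <- add_substitutions_vec(s2, error_rate)
    pairs <- tibble::tibble(
      read_id = sprintf("sim_%06d", seq_len(n_reads)),
      seq1 = s1, qual1 = vapply(nchar(s1), random_quals, character(1)),
      seq2 = s2, qual2 = vapply(nchar(s2), random_quals, character(1))
    )
    truth <- tibble::tibble(
      read_id = pairs$read_id,
      left_del = specs$left_del[draw], right_del = specs$right_del[draw],
      mh_len = specs$mh_len[draw], ins_seq = specs$ins_seq[draw],
      phasing = phase, spec_index = draw
    )
    list(pairs = pairs, truth = truth)
  })
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Writes gzipped paired FASTQ, the reference FASTA, a JSON locus config
#' and a TSV truth manifest — everything needed to run the full pipeline
#' offline against known ground truth.
#'
#' @param dir Output directory (created if needed).
#' @inheritParams simulate_scar_library
#' @return Invisibly, a named list of the file paths written.
#' @export
write_fixture_bundle <- function(dir, locus, mixture, n_reads,
                                 read_len = 300L, error_rate = 0.001,
                                 phasing_max = 8L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lib <- simulate_scar_library(locus, mixture, n_reads, read_len = read_len,
                               error_rate = error_rate,
                               phasing_max = phasing_max, seed = seed)
  paths <- list(
    fastq1 = file.path(dir, "reads_R1.fastq.gz"),
    fastq2 = file.path(dir, "reads_R2.fastq.gz"),
    fasta = file.path(dir, "reference.fasta"),
    config = file.path(dir, "locus.json"),
    truth = file.path(dir, "truth_manifest.tsv")
  )
  write_fastq_pairs(lib$pairs, paths$fastq1, paths$fastq2)
  ref <- Biostrings::DNAStringSet(locus$sequence)
  names(ref) <- locus$name
  Biostrings::writeXStringSet(ref, paths$fasta)
  jsonlite::write_json(
    list(name = locus$name, cut_index = locus$cut_index,
         kmer_size = locus$kmer_size,
         donor_marker = locus$donor_marker, seed = seed, n_reads = n_reads,
         read_len = read_len, error_rate = error_rate,
         phasing_max = phasing_max),
    paths$config, auto_unbox = TRUE, null = "null"
  )
  utils::write.table(lib$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Canonical signature-product fixtures
#'
#' Three engineered loci with known junctions, matching the signature
#' repair products used for pathway-specific assays: a 23 bp total deletion
#' with 6 bp microhomology (TMEJ), a 95 bp total deletion with 5 bp
#' microhomology (TMEJ), and a single-T insertion (NHEJ) at a locus whose
#' first downstream base is not T (so the insertion is unambiguous).
#'
#' @param seed Base seed for the locus generators.
#' @return Named list (`tmej23`, `tmej95`, `nhej_ins1`); each element has
#'   `locus`, `consensus` (the error-free scarred read) and `truth`.
#' @export
signature_fixtures <- function(seed = 1L) {
  tmej23_locus <- make_mh_locus(seed = seed, motif_len = 6L, left_gap = 9L,
                                right_gap = 8L, anchor_len = c(15L, 16L))
  tmej95_locus <- make_mh_locus(seed = seed + 1L, motif_len = 5L,
                                left_gap = 45L, right_gap = 45L,
                                anchor_len = c(60L, 60L))
  ins_locus <- with_seed_local(seed + 2L, {
    repeat {
      loc <- make_locus(flank_len = 60L)
      if (stringr::str_sub(loc$sequence, loc$cut_index + 1L,
                           loc$cut_index + 1L) != "T") break
    }
    loc
  })
  fixture <- function(locus, left, right, mh, ins) {
    truth <- tibble::tibble(left_del = as.integer(left),
                            right_del = as.integer(right),
                            mh_len = as.integer(mh), ins_seq = ins)
    list(locus = locus,
         consensus = apply_scar(locus, left, right, mh, ins),
         truth = truth)
  }
  list(
    tmej23 = fixture(tmej23_locus, 9L, 8L, 6L, ""),
    tmej95 = fixture(tmej95_locus, 45L, 45L, 5L, ""),
    nhej_ins1 = fixture(ins_locus, 0L, 0L, 0L, "T")
  )
}
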