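test_that("generated loci have unique k-mers and are seed-reproducible", {
  loc <- make_locus(seed = 1, flank_len = 100, kmer_size = 10)
  kmers <- scarcall:::all_kmers(loc$sequence, 10)
  expect_identical(anyDuplicated(kmers), 0L)      # exhaustive k-mer census
  expect_identical(nchar(loc$sequence), 200L)
  expect_identical(loc$cut_index, 100L)
  loc2 <- make_locus(seed = 1, flank_len = 100, kmer_size = 10)
  expect_identical(loc2$sequence, loc$sequence)
  expect_error(make_locus(seed = 1, flank_len = 12), "flank_len")
})

test_that("microhomology loci carry the motif exactly twice", {
  loc <- make_mh_locus(seed = 2, motif_len = 6, left_gap = 9, right_gap = 8,
                       anchor_len = c(15, 16))
  expect_identical(nchar(loc$sequence), 15L + 6L + 9L + 8L + 6L + 16L)
  expect_identical(loc$cut_index, 30L)
  occ <- scarcall:::kmer_occurrences(loc$sequence, loc$motif)
  expect_identical(length(occ), 2L)
  # a reference missing the second motif copy is rejected
  one_copy <- paste0(substring(loc$sequence, 1, 37),
                     substring(strrep("A", 6), 1, 6),
                     substring(loc$sequence, 44, 60))
  expect_error(scarcall:::validate_mh_reference(one_copy, loc$motif, 10),
               "exactly twice")
  expect_error(make_mh_locus(seed = 1, motif_len = 12, left_gap = 5,
                             right_gap = 5, anchor_len = 20),
               "smaller than kmer_size")
})

test_that("apply_scar validates junction geometry", {
  loc <- small_locus()
  expect_identical(apply_scar(loc), loc$sequence)
  expect_identical(
    apply_scar(loc, 3, 2, 0, "GG"),
    paste0(substring(loc$sequence, 1, 27), "GG", substring(loc$sequence, 33, 60))
  )
  expect_error(apply_scar(loc, 100, 0), "does not fit")
  expect_error(apply_scar(loc, 0, 0, 3, "T"), "both a microhomology")
  # the reference must carry the repeat pair for an MH junction
  expect_error(apply_scar(loc, 2, 2, 3), "repeat pair")
  mh_loc <- make_mh_locus(seed = 2, motif_len = 6, left_gap = 9,
                          right_gap = 8, anchor_len = c(15, 16))
  expect_identical(apply_scar(mh_loc, 9, 8, 6),
                   paste0(substring(mh_loc$sequence, 1, 21),
                          substring(mh_loc$sequence, 45, 60)))
})

test_that("single read pairs reconstruct the scarred amplicon", {
  loc <- make_locus(seed = 3, flank_len = 100)
  spec <- list(left_del = 0L, right_del = 0L, mh_len = 0L, ins_seq = "")
  pair <- make_read_pair(loc, spec, read_len = 150, error_rate = 0, seed = 5)
  m <- merge_pairs(pair)
  expect_true(m$merged)
  # consensus is the unedited reference behind its phasing prefix
  expect_identical(substring(m$seq, pair$phasing + 1), loc$sequence)
  expect_identical(call_junctions(m$seq, loc)$status, "NO_SCAR")
  expect_lte(pair$phasing, 8L)
  pair2 <- make_read_pair(loc, spec, read_len = 150, error_rate = 0, seed = 5)
  expect_identical(pair2, pair)
})

test_that("library simulation is deterministic end-to-end under a seed", {
  loc <- make_locus(seed = 4, flank_len = 80)
  mix <- tibble::tibble(left_del = 5L, right_del = 3L, mh_len = 0L,
                        ins_seq = "", frequency = 0.5)
  a <- simulate_scar_library(loc, mix, 40, read_len = 120, seed = 9)
  b <- simulate_scar_library(loc, mix, 40, read_len = 120, seed = 9)
  expect_identical(a, b)
  expect_identical(nrow(a$pairs), 40L)
  expect_true(all(a$truth$phasing <= 8))
  expect_error(
    simulate_scar_library(loc, dplyr::mutate(mix, frequency = 1.2), 10),
    "more than 1")
})

test_that("error-free reads round-trip through the caller to their spec", {
  set.seed(71)
  n_cases <- 0
  for (rep in 1:6) {
    loc <- make_locus(flank_len = 90)
    for (j in 1:10) {
      spec <- random_spec(loc, max_del = 35)
      lib <- simulate_scar_library(
        loc, dplyr::mutate(spec, frequency = 1), 1, read_len = 140,
        error_rate = 0, seed = 1000 + n_cases)
      m <- merge_pairs(lib$pairs)
      call <- call_junctions(m, loc)
      # truth canonicalised through the independent brute-force oracle:
      # chance repeats at the junction can trade deletion for microhomology
      consensus_truth <- apply_scar(loc, spec$left_del, spec$right_del, 0,
                                    spec$ins_seq)
      ora <- oracle_decompose(consensus_truth, loc)
      expect_identical(call$status, ora$status)
      if (ora$status == "SCAR") {
        expect_identical(call$total_del, as.integer(ora$total_del))
        expect_identical(call$mh_seq, ora$mh_seq)
        expect_identical(call$ins_seq, ora$ins_seq)
      }
      n_cases <- n_cases + 1
    }
  }
  expect_identical(as.integer(n_cases), 60L)
})

test_that("fixture bundles regenerate byte-identically from a seed", {
  loc <- make_locus(seed = 6, flank_len = 70)
  mix <- tibble::tibble(left_del = 4L, right_del = 0L, mh_len = 0L,
                        ins_seq = "", frequency = 0.6)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- suppressWarnings(write_fixture_bundle(d1, loc, mix, 20,
                                              read_len = 100, seed = 7))
  p2 <- suppressWarnings(write_fixture_bundle(d2, loc, mix, 20,
                                              read_len = 100, seed = 7))
  for (f in c("truth", "config")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  r1 <- read_fastq_pairs(p1$fastq1, p1$fastq2)
  r2 <- read_fastq_pairs(p2$fastq1, p2$fastq2)
  expect_identical(r1, r2)
  cfg <- jsonlite::read_json(p1$config)
  expect_identical(cfg$cut_index, loc$cut_index)
  expect_identical(cfg$seed, 7L)
})
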