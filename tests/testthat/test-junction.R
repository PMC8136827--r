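test_that("unedited reads anchor both flanks at zero deletion", {
  loc <- small_locus()
  d <- build_flank_dictionaries(loc)
  uf <- find_flank(loc$sequence, d$upstream)
  expect_true(uf$found)
  expect_identical(uf$deletion, 0L)
  expect_identical(uf$match_start, loc$cut_index - loc$kmer_size)
  df <- find_flank(loc$sequence, d$downstream,
                   search_from = uf$match_end - loc$kmer_size + 2L)
  expect_identical(df$deletion, 0L)
  expect_identical(df$match_start, loc$cut_index)
  expect_identical(call_junctions(loc$sequence, loc)$status, "NO_SCAR")
})

test_that("the engineered 23 bp microhomology junction decomposes exactly", {
  loc <- make_mh_locus(seed = 1, motif_len = 6, left_gap = 9, right_gap = 8,
                       anchor_len = c(15, 16))
  consensus <- apply_scar(loc, 9, 8, 6, "")
  d <- build_flank_dictionaries(loc)

  uf <- find_flank(consensus, d$upstream)
  expect_identical(uf$deletion, 9L)
  df <- find_flank(consensus, d$downstream,
                   search_from = uf$match_end - loc$kmer_size + 2L)
  expect_identical(df$deletion, 8L)

  # brute-force scan of every dictionary entry confirms both minima
  ora_u <- oracle_flank(consensus, d$upstream)
  ora_d <- oracle_flank(consensus, d$downstream,
                        search_from = ora_u$match_end - loc$kmer_size + 2)
  expect_identical(uf$deletion, as.integer(ora_u$deletion))
  expect_identical(df$deletion, as.integer(ora_d$deletion))

  call <- call_junctions(consensus, loc)
  expect_identical(call$status, "SCAR")
  expect_identical(call$left_del, 9L)
  expect_identical(call$right_del, 8L)
  expect_identical(call$mh_seq, loc$motif)
  expect_identical(call$ins_seq, "")
  expect_identical(call$total_del, 23L)
})

test_that("a single inserted base at the cut is called as a 1-nt insertion", {
  fx <- signature_fixtures(seed = 1)$nhej_ins1
  call <- call_junctions(fx$consensus, fx$locus)
  expect_identical(call$status, "SCAR")
  expect_identical(call$left_del, 0L)
  expect_identical(call$right_del, 0L)
  expect_identical(call$mh_seq, "")
  expect_identical(call$ins_seq, "T")
  expect_identical(call$total_del, 0L)
})

test_that("the donor gene-conversion marker takes precedence as HR", {
  loc0 <- small_locus()
  marker <- "GGATCCGTCGACAT"
  loc <- target_locus(loc0$sequence, 30, donor_marker = marker)
  hr_read <- paste0(substring(loc$sequence, 1, 30), marker,
                    substring(loc$sequence, 31, 60))
  call <- call_junctions(hr_read, loc)
  expect_identical(call$status, "HR")
  expect_identical(call_junctions(loc$sequence, loc)$status, "NO_SCAR")
})

test_that("unresolvable reads are flagged, not guessed", {
  loc <- small_locus()
  short <- substring(loc$sequence, 25, 40)
  call <- call_junctions(short, loc)
  expect_identical(call$status, "UNRESOLVED")
  expect_identical(call$reason, "too short")
  # a read with no upstream flank at any deletion depth
  set.seed(3)
  alien <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                 collapse = "")
  noup <- paste0(alien, substring(loc$sequence, 31, 60))
  call2 <- call_junctions(noup, loc)
  expect_identical(call2$status, "UNRESOLVED")
})

test_that("N bases inside a flank window void that match", {
  loc <- small_locus()
  read <- loc$sequence
  # corrupt the d=0 upstream window with an N: caller must fall back to d=1
  substring(read, 25, 25) <- "N"
  call <- call_junctions(read, loc)
  expect_identical(call$status, "SCAR")
  expect_gt(call$left_del + nchar(call$mh_seq), 0L)
})

test_that("substitutions distal to the junction 20-mer do not change calls", {
  loc <- make_mh_locus(seed = 1, motif_len = 6, left_gap = 9, right_gap = 8,
                       anchor_len = c(30, 30))
  consensus <- apply_scar(loc, 9, 8, 6, "")
  baseline <- call_junctions(consensus, loc)
  d <- build_flank_dictionaries(loc)
  uf <- oracle_flank(consensus, d$upstream)
  df <- oracle_flank(consensus, d$downstream,
                     search_from = uf$match_end - loc$kmer_size + 2)
  near <- (uf$match_start - 9):(df$match_end + 10) + 1  # 1-based guard zone
  far <- setdiff(seq_len(nchar(consensus)), near)
  set.seed(9)
  for (i in 1:25) {
    mutated <- consensus
    for (p in sample(far, 3)) {
      old <- substring(mutated, p, p)
      substring(mutated, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
    call <- call_junctions(mutated, loc)
    expect_identical(call[-1], baseline[-1])  # identical up to read_id
  }
})

test_that("calls are deterministic and reconstruct the read", {
  loc <- make_locus(seed = 51, flank_len = 80)
  set.seed(52)
  for (i in 1:20) {
    spec <- random_spec(loc, max_del = 30)
    consensus <- apply_scar(loc, spec$left_del, spec$right_del, 0, spec$ins_seq)
    c1 <- call_junctions(consensus, loc)
    c2 <- call_junctions(consensus, loc)
    expect_identical(c1, c2)
    expect_identical(c1$status, if (spec$left_del + spec$right_del +
                                      nchar(spec$ins_seq) == 0) "NO_SCAR" else "SCAR")
    expect_true(oracle_reconstructs(consensus, loc, as.list(c1)))
    # microhomology and insertion are mutually exclusive
    expect_false(nchar(c1$mh_seq) > 0 && nchar(c1$ins_seq) > 0)
  }
})

test_that("flank choices are minimal against the brute-force oracle", {
  set.seed(61)
  n_checked <- 0
  for (rep in 1:12) {
    loc <- make_locus(flank_len = sample(60:140, 1))  # amplicons <= 280 nt
    dicts <- build_flank_dictionaries(loc)
    for (j in 1:5) {
      spec <- random_spec(loc)
      consensus <- apply_scar(loc, spec$left_del, spec$right_del, 0,
                              spec$ins_seq)
      call <- call_junctions(consensus, loc)
      ora <- oracle_decompose(consensus, loc)
      expect_identical(call$status, ora$status)
      if (call$status == "SCAR") {
        expect_identical(call$left_del, as.integer(ora$left_del))
        expect_identical(call$right_del, as.integer(ora$right_del))
        expect_identical(call$mh_seq, ora$mh_seq)
        expect_identical(call$ins_seq, ora$ins_seq)
      }
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 60)
})
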