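#' Assign repair-pathway labels to scar calls
#'
#' Pathway definitions (applied in order, so every scarred read gets exactly
#' one label):
#' \itemize{
#'   \item `HR` — read carried the donor gene-conversion marker.
#'   \item `INSERTION` — insertion >= 5 nt, regardless of associated
#'     deletion size.
#'   \item `TMEJ` — total deletion >= 4 nt with microhomology >= 2 nt
#'     (polymerase-theta-mediated end joining).
#'   \item `NON_MH_EJ` — total deletion >= 4 nt, microhomology < 2 nt.
#'   \item `NHEJ` — deletion < 4 nt and insertion < 5 nt.
#' }
#'
#' @param calls Tibble of scar calls from [call_junctions()] (rows with
#'   status other than SCAR/HR are passed through with pathway `NA`), or a
#'   tibble with columns `total_del`, `mh_seq` (or `mh_len`), `ins_seq` (or
#'   `ins_len`).
#' @return The input tibble with a `pathway` column added.
#' @examples
#' classify_scars(tibble::tibble(total_del = 23, mh_len = 6, ins_len = 0))
#' @export
classify_scars <- function(calls) {
  calls <- tibble::as_tibble(calls)
  mh_len <- if ("mh_len" %in% names(calls)) calls$mh_len else nchar(calls$mh_seq)
  ins_len <- if ("ins_len" %in% names(calls)) calls$ins_len else nchar(calls$ins_seq)
  status <- if ("status" %in% names(calls)) calls$status else
    rep("SCAR", nrow(calls))
  pathway <- dplyr::case_when(
    status == "HR" ~ "HR",
    status %in% c("NO_SCAR", "UNRESOLVED") ~ NA_character_,
    ins_len >= 5L ~ "INSERTION",
    calls$total_del >= 4L & mh_len >= 2L ~ "TMEJ",
    calls$total_del >= 4L ~ "NON_MH_EJ",
    TRUE ~ "NHEJ"
  )
  dplyr::mutate(calls, pathway = pathway)
}

pathway_levels <- c("NHEJ", "NON_MH_EJ", "TMEJ", "INSERTION", "HR")

#' Tabulate unique repair patterns and their frequencies
#'
#' Patterns are keyed exactly by (left deletion, right deletion,
#' microhomology sequence, insertion sequence). Frequencies are computed
#' over scarred reads only — SCAR plus (by default) HR calls — because a
#' large fraction of unedited reads come from uncut chromosomes; NO_SCAR
#' and UNRESOLVED reads are excluded from the denominator but retained in
#' the totals for read accounting.
#'
#' @param calls Tibble of scar calls from [call_junctions()]; a `merged`
#'   logical column (from a merged [merge_pairs()] table that retained
#'   unmerged rows) contributes to the totals.
#' @param label Sample label stored with the table.
#' @param include_hr Include HR reads in the frequency denominator (default
#'   TRUE, so HR appears on the same axis as end-joining products).
#' @param n_unmerged Number of read pairs that failed merging, if merging
#'   was done outside this call (added to the totals).
#' @return A `scar_freq_table`: a tibble with one row per unique pattern
#'   (`left_del`, `right_del`, `mh_seq`, `ins_seq`, `total_del`, `pathway`,
#'   `count`, `frequency`), ordered by descending frequency then key, with
#'   attributes `label` and `totals`.
#' @export
tabulate_scars <- function(calls, label = "sample", include_hr = TRUE,
                           n_unmerged = 0L) {
  calls <- classify_scars(calls)
  statuses <- c("SCAR", if (include_hr) "HR")
  totals <- c(
    reads_in = nrow(calls) + as.integer(n_unmerged),
    unmerged = as.integer(n_unmerged),
    no_scar = sum(calls$status == "NO_SCAR"),
    unresolved = sum(calls$status == "UNRESOLVED"),
    hr = sum(calls$status == "HR"),
    scarred = sum(calls$status %in% statuses)
  )
  kept <- dplyr::filter(calls, .data$status %in% statuses)
  if (nrow(kept) == 0L) {
    warning("no scarred reads in sample '", label, "'; empty frequency table",
            call. = FALSE)
    tab <- tibble::tibble(
      left_del = integer(), right_del = integer(), mh_seq = character(),
      ins_seq = character(), total_del = integer(), pathway = character(),
      count = integer(), frequency = double()
    )
  } else {
    tab <- kept |>
      dplyr::count(.data$left_del, .data$right_del, .data$mh_seq,
                   .data$ins_seq, .data$total_del, .data$pathway,
                   name = "count") |>
      dplyr::mutate(frequency = .data$count / sum(.data$count)) |>
      dplyr::arrange(dplyr::desc(.data$frequency), .data$left_del,
                     .data$right_del, .data$mh_seq, .data$ins_seq)
  }
  new_scar_freq_table(tab, label = label, totals = totals)
}

new_scar_freq_table <- function(tab, label, totals) {
  structure(tab, label = label, totals = totals,
            class = c("scar_freq_table", class(tab)))
}

#' @export
print.scar_freq_table <- function(x, ...) {
  t <- attr(x, "totals")
  cat("<scar_freq_table> ", attr(x, "label"), ": ", nrow(x),
      " unique repair patterns over ", t[["scarred"]], " scarred reads\n",
      sep = "")
  cat("  reads in ", t[["reads_in"]], " | unmerged ", t[["unmerged"]],
      " | no scar ", t[["no_scar"]], " | unresolved ", t[["unresolved"]],
      "\n", sep = "")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a scar frequency table into a plain tibble
#' @param x A `scar_freq_table`.
#' @param ... Unused.
#' @export
tidy.scar_freq_table <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(sample = attr(x, "label"), .before = 1L)
}

#' One-row read-accounting summary of a scar frequency table
#' @param x A `scar_freq_table`.
#' @param ... Unused.
#' @export
glance.scar_freq_table <- function(x, ...) {
  t <- as.list(attr(x, "totals"))
  tibble::as_tibble(t) |>
    dplyr::mutate(sample = attr(x, "label"), n_patterns = nrow(x),
                  .before = 1L)
}

#' Pol theta-dependency ratios between a sample and a Polq-null control
#'
#' For each repair pattern, the ratio of its frequency in the sample to its
#' frequency in the Pol theta-deficient control. Patterns absent from the
#' control are floored at `pseudocount` (default one read over the
#' control's scarred-read total) so ratios stay finite, and are marked
#' `absent_in_null`. Ratios >= 2 flag Pol theta-dependent products.
#'
#' @param sample,polq_null `scar_freq_table`s for the sample and the
#'   Polq-deficient control.
#' @param pseudocount Frequency floor applied to the control; default
#'   `1 / scarred-read total of the control`.
#' @return Tibble with the pattern key, both frequencies, `ratio`,
#'   `theta_dependent` (ratio >= 2) and `absent_in_null`.
#' @export
theta_dependency <- function(sample, polq_null, pseudocount = NULL) {
  stopifnot(inherits(sample, "scar_freq_table"),
            inherits(polq_null, "scar_freq_table"))
  if (nrow(sample) == 0L || nrow(polq_null) == 0L) {
    stop("both frequency tables must be nonempty", call. = FALSE)
  }
  if (is.null(pseudocount)) {
    pseudocount <- 1 / attr(polq_null, "totals")[["scarred"]]
  }
  key <- c("left_del", "right_del", "mh_seq", "ins_seq")
  null_tab <- tibble::as_tibble(polq_null)[c(key, "frequency")] |>
    dplyr::rename(null_frequency = "frequency")
  tibble::as_tibble(sample) |>
    dplyr::left_join(null_tab, by = key) |>
    dplyr::mutate(
      absent_in_null = is.na(.data$null_frequency),
      ratio = .data$frequency / pmax(.data$null_frequency, pseudocount,
                                     na.rm = TRUE),
      theta_dependent = .data$ratio >= 2
    ) |>
    dplyr::select(dplyr::all_of(key), "total_del", "pathway", "frequency",
                  "null_frequency", "ratio", "theta_dependent",
                  "absent_in_null")
}

#' Write a frequency table as TSV
#' @param table A `scar_freq_table`.
#' @param file Output path.
#' @export
write_freq_table <- function(table, file) {
  utils::write.table(tibble::as_tibble(table), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
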