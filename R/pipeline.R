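#' Run the full scar-calling pipeline on a paired FASTQ library
#'
#' Streams read pairs, merges them into consensus reads, decomposes each
#' consensus at the cut site, classifies pathways and tabulates pattern
#' frequencies. When `out_dir` is given, writes the per-read calls (TSV),
#' the frequency table (TSV + JSON), the scar-spectrum figure (SVG with
#' companion TSV), a pathway summary and a machine-readable provenance
#' block.
#'
#' @param fastq1,fastq2 Paired FASTQ paths (optionally gzipped).
#' @param locus A [target_locus()].
#' @param label Sample label.
#' @param min_overlap,max_mismatch_frac Merge parameters (see
#'   [merge_pairs()]).
#' @param min_frequency Spectrum display cutoff (see
#'   [plot_scar_spectrum()]).
#' @param include_hr Include HR reads in frequency denominators.
#' @param out_dir Optional output directory.
#' @return A list of class `scar_run`: `table` (the `scar_freq_table`),
#'   `calls` (per-read scar calls), `pathways` (aggregate frequencies) and
#'   `accounting` (read totals).
#' @export
scar_pipeline <- function(fastq1, fastq2, locus, label = "sample",
                          min_overlap = 20L, max_mismatch_frac = 0.1,
                          min_frequency = 0.00025, include_hr = TRUE,
                          out_dir = NULL) {
  pairs <- read_fastq_pairs(fastq1, fastq2)
  if (nrow(pairs) == 0L) {
    warning("no reads in ", fastq1, call. = FALSE)
    merged <- tibble::tibble(read_id = character(), merged = logical(),
                             seq = character(), qual = character())
  } else {
    merged <- merge_pairs(pairs, min_overlap = min_overlap,
                          max_mismatch_frac = max_mismatch_frac)
  }
  consensus <- dplyr::filter(merged, .data$merged)
  calls <- call_junctions(consensus, locus)
  calls <- classify_scars(calls)
  table <- tabulate_scars(calls, label = label, include_hr = include_hr,
                          n_unmerged = sum(!merged$merged))
  pathways <- summarize_by_pathway(table)
  run <- structure(
    list(table = table, calls = calls, pathways = pathways,
         accounting = attr(table, "totals")),
    class = "scar_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(calls, file.path(out_dir, "scar_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_freq_table(table, file.path(out_dir, "frequency_table.tsv"))
    jsonlite::write_json(
      list(label = label, totals = as.list(attr(table, "totals")),
           patterns = tibble::as_tibble(table)),
      file.path(out_dir, "frequency_table.json"),
      auto_unbox = TRUE, digits = NA
    )
    utils::write.table(pathways, file.path(out_dir, "pathway_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(table) > 0L) {
      write_scar_spectrum(table, file.path(out_dir, "scar_spectrum.svg"),
                          min_frequency = min_frequency)
    }
    jsonlite::write_json(
      list(tool = "scarcall",
           version = as.character(utils::packageVersion("scarcall")),
           fastq1 = fastq1, fastq2 = fastq2, locus = locus$name,
           cut_index = locus$cut_index, kmer_size = locus$kmer_size,
           donor_marker = locus$donor_marker, min_overlap = min_overlap,
           max_mismatch_frac = max_mismatch_frac,
           min_frequency = min_frequency, include_hr = include_hr,
           timestamp = format(Sys.time(), tz = "UTC")),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, null = "null"
    )
  }
  run
}

#' @export
print.scar_run <- function(x, ...) {
  cat("<scar_run>\n")
  acc <- x$accounting
  cat("  reads in:", acc[["reads_in"]], " unmerged:", acc[["unmerged"]],
      " no scar:", acc[["no_scar"]], " unresolved:", acc[["unresolved"]],
      " scarred:", acc[["scarred"]], "\n")
  cat("  ", nrow(x$table), " unique repair patterns; pathway frequencies:\n",
      sep = "")
  print(x$pathways)
  invisible(x)
}
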