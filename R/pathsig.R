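#' Poisson concentration estimate from droplet counts
#'
#' In droplet digital PCR, target molecules partition into droplets
#' approximately Poisson, so the mean copies per droplet is
#' `lambda = -ln(1 - p)` where `p` is the positive-droplet fraction. The
#' confidence interval is the Wilson score interval on `p` propagated
#' through the same transform (the Wilson interval stays well-behaved near
#' zero positives).
#'
#' @param positives,total Integer vectors of positive and total droplet
#'   counts per reaction (recycled to common length). `positives == total`
#'   (saturated wells) is rejected.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return Tibble with `positives`, `total`, `lambda`, `lambda_lower`,
#'   `lambda_upper`.
#' @examples
#' poisson_lambda(12642, 20000)  # p ~ 1 - e^-1, lambda ~ 1
#' @export
poisson_lambda <- function(positives, total, conf_level = 0.95) {
  n <- max(length(positives), length(total))
  positives <- as.integer(rep_len(positives, n))
  total <- as.integer(rep_len(total, n))
  if (any(total <= 0L)) stop("total droplet count must be positive", call. = FALSE)
  if (any(positives < 0L | positives > total)) {
    stop("positives must lie in [0, total]", call. = FALSE)
  }
  if (any(positives == total)) {
    stop("saturated reaction (positives == total): lambda is unbounded; ",
         "dilute and re-run", call. = FALSE)
  }
  ci <- purrr::map2(positives, total, function(x, n) {
    if (x == 0L) {
      # Wilson upper bound still defined at zero positives
      up <- stats::prop.test(x, n, conf.level = conf_level,
                             correct = FALSE)$conf.int[2L]
      c(0, up)
    } else {
      stats::prop.test(x, n, conf.level = conf_level,
                       correct = FALSE)$conf.int
    }
  })
  p <- positives / total
  tibble::tibble(
    positives = positives, total = total,
    lambda = -log1p(-p),
    lambda_lower = -log1p(-purrr::map_dbl(ci, 1L)),
    lambda_upper = -log1p(-purrr::map_dbl(ci, 2L))
  )
}

#' Percent repair from signature and reference droplet channels
#'
#' The PathSig quantification: the signature repair product's concentration
#' is normalized to 100 copies of genomic DNA as measured by a reference
#' amplicon assay, `percent_repair = 100 * lambda_sig / lambda_ref`. The
#' confidence interval comes from the delta method on the log ratio of the
#' two independent Poisson estimates.
#'
#' Replicate wells should be pooled (counts summed) before calling.
#'
#' @param sig_positives,sig_total Droplet counts for the signature channel.
#' @param ref_positives,ref_total Droplet counts for the genomic reference
#'   channel.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble with `lambda_sig`, `lambda_ref`, `percent_repair`,
#'   `pr_lower`, `pr_upper`.
#' @examples
#' percent_repair(5000, 20000, 5000, 20000)  # equal channels -> 100
#' @export
percent_repair <- function(sig_positives, sig_total, ref_positives, ref_total,
                           conf_level = 0.95) {
  sig <- poisson_lambda(sig_positives, sig_total, conf_level)
  ref <- poisson_lambda(ref_positives, ref_total, conf_level)
  stopifnot(nrow(sig) == 1L, nrow(ref) == 1L)
  if (ref$lambda == 0) {
    stop("reference channel has zero concentration: normalization undefined",
         call. = FALSE)
  }
  pr <- 100 * sig$lambda / ref$lambda
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_log <- function(x, n) {
    p <- x / n
    lam <- -log1p(-p)
    if (x == 0L) return(NA_real_)
    sqrt(p * (1 - p) / n) / ((1 - p) * lam)  # se of log(lambda), delta method
  }
  s1 <- se_log(sig$positives, sig$total)
  s2 <- se_log(ref$positives, ref$total)
  if (is.na(s1)) {
    lower <- 0
    upper <- 100 * sig$lambda_upper / ref$lambda
  } else {
    se <- sqrt(s1^2 + s2^2)
    lower <- pr * exp(-z * se)
    upper <- pr * exp(z * se)
  }
  tibble::tibble(
    lambda_sig = sig$lambda, lambda_ref = ref$lambda,
    percent_repair = pr, pr_lower = lower, pr_upper = upper
  )
}

#' Quantify percent repair for a table of droplet counts
#'
#' Tidy front end over [percent_repair()]: takes long-format droplet counts
#' with one row per (sample, channel) reaction, pools replicate wells by
#' summation, and returns one row per sample.
#'
#' @param counts Data frame with columns `sample`, `channel`, `positives`,
#'   `total`.
#' @param signature,reference The channel labels of the signature-product
#'   and genomic-reference assays.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with one row per sample: pooled counts, lambdas and
#'   `percent_repair` with its interval.
#' @export
quantify_repair <- function(counts, signature = "signature",
                            reference = "reference", conf_level = 0.95) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("sample", "channel", "positives", "total") %in% names(counts)))
  missing_ch <- setdiff(c(signature, reference), unique(counts$channel))
  if (length(missing_ch) > 0L) {
    stop("channel(s) not present in counts: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  pooled <- counts |>
    dplyr::filter(.data$channel %in% c(signature, reference)) |>
    dplyr::group_by(.data$sample, .data$channel) |>
    dplyr::summarise(positives = sum(.data$positives),
                     total = sum(.data$total), .groups = "drop")
  pooled |>
    tidyr::pivot_wider(names_from = "channel",
                       values_from = c("positives", "total")) |>
    dplyr::rowwise() |>
    dplyr::mutate(percent_repair(
      .data[[paste0("positives_", signature)]],
      .data[[paste0("total_", signature)]],
      .data[[paste0("positives_", reference)]],
      .data[[paste0("total_", reference)]],
      conf_level = conf_level
    )) |>
    dplyr::ungroup()
}

#' Read a droplet-count CSV
#'
#' Expected columns: `sample`, `channel`, `positives`, `total` (one row per
#' reaction well).
#'
#' @param file CSV path.
#' @return Tibble of droplet counts.
#' @export
read_droplet_csv <- function(file) {
  if (!file.exists(file)) stop("droplet CSV not found: ", file, call. = FALSE)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("sample", "channel", "positives", "total")
  if (!all(need %in% names(df))) {
    stop("droplet CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(is.na(df$positives) | is.na(df$total) | df$total <= 0 |
                 df$positives < 0 | df$positives > df$total)
  if (length(bad) > 0L) {
    stop("malformed droplet counts at CSV line ", bad[1L] + 1L, call. = FALSE)
  }
  tibble::as_tibble(df)
}
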