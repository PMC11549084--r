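#' Pollen-FISH drive-frequency statistics
#'
#' After the first pollen mitosis (PMI), a driving B chromosome undergoes
#' nondisjunction and its chromatids accumulate in the generative nucleus,
#' ending up only in the sperm nuclei (SN) after PMII. Pollen-FISH scores each
#' pollen grain into four signal classes: no B-specific signal (meiotic or
#' post-meiotic B loss), signal only in the vegetative nucleus (VN), signal
#' only in the sperm nuclei, or signal in all nuclei (normal disjunction).
#' The drive frequency is the fraction of signal-bearing pollen whose signal
#' is confined to the sperm nuclei:
#'
#' \deqn{f = sn / (vn + sn + all)}
#'
#' @name drive-stats
NULL

#' Validate a pollen-FISH count row
#'
#' Checks that all counts are non-negative and that the four signal classes
#' add up to the stated total.
#'
#' @param row A list or data frame row with numeric fields `total`, `none`,
#'   `vn_only`, `sn_only`, `all_nuclei`.
#' @return `TRUE` (invisibly) if the row is consistent; otherwise an error
#'   whose message reports the discrepancy `total - (none + vn + sn + all)`.
#' @examples
#' validate_row(list(total = 77, none = 15, vn_only = 3,
#'                   sn_only = 55, all_nuclei = 4))
#' @export
validate_row <- function(row) {
  fields <- c("total", "none", "vn_only", "sn_only", "all_nuclei")
  missing <- setdiff(fields, names(row))
  if (length(missing) > 0L) {
    stopf("pollen row is missing fields: %s", paste(missing, collapse = ", "))
  }
  counts <- vapply(fields, function(f) as.numeric(row[[f]]), numeric(1))
  if (any(is.na(counts))) stopf("pollen row contains missing counts")
  if (any(counts < 0)) stopf("pollen row contains negative counts")
  discrepancy <- counts[["total"]] -
    sum(counts[c("none", "vn_only", "sn_only", "all_nuclei")])
  if (discrepancy != 0) {
    stopf("pollen row inconsistent: total differs from class sum by %g",
          discrepancy)
  }
  invisible(TRUE)
}

#' Drive frequency from a pollen-FISH count row
#'
#' Computes the drive frequency `sn_only / (vn_only + sn_only + all_nuclei)`
#' (pollen without any B signal are excluded from the denominator because B
#' loss before PMI is uninformative about drive), together with a Wilson
#' score confidence interval and a yes/no drive call.
#'
#' The drive call uses a 0.5 threshold: under symmetric (Mendelian)
#' segregation at PMI, B signal confined to the sperm nuclei and B signal in
#' all nuclei are the null expectation's extremes, and observed frequencies
#' in real karyotypes are strongly bimodal (0 percent versus near 90
#' percent), so any cut in between reproduces the calls; 0.5 is the neutral
#' choice. The full interval is reported so stricter rules can be applied.
#'
#' @inheritParams validate_row
#' @param conf Confidence level of the Wilson interval (default 0.95).
#' @return A list of class `drive_estimate` with elements `frequency`,
#'   `percent` (half-up rounded to one decimal), `ci` (length-2 numeric),
#'   `drive_call` (`"yes"`/`"no"`), and the denominator `n_informative`.
#'   When no pollen carries a B signal the frequency is `NA` and
#'   `drive_call` is `"undefined"`.
#' @examples
#' drive_frequency(list(total = 77, none = 15, vn_only = 3,
#'                      sn_only = 55, all_nuclei = 4))$percent  # 88.7
#' @export
drive_frequency <- function(row, conf = 0.95) {
  validate_row(row)
  sn <- as.numeric(row$sn_only)
  denom <- as.numeric(row$vn_only) + sn + as.numeric(row$all_nuclei)
  if (denom == 0) {
    out <- list(frequency = NA_real_, percent = NA_real_,
                ci = c(NA_real_, NA_real_), drive_call = "undefined",
                n_informative = 0)
    class(out) <- "drive_estimate"
    return(out)
  }
  freq <- sn / denom
  ci <- wilson_ci(sn, denom, conf = conf)
  out <- list(frequency = freq,
              percent = round_half_up(100 * freq, 1),
              ci = ci,
              drive_call = if (freq > 0.5) "yes" else "no",
              n_informative = denom)
  class(out) <- "drive_estimate"
  out
}

#' @export
print.drive_estimate <- function(x, ...) {
  if (is.na(x$frequency)) {
    cat("drive frequency: undefined (no signal-bearing pollen)\n")
  } else {
    cat(sprintf("drive frequency: %.1f%% (n = %d, 95%% CI %.1f-%.1f%%), drive: %s\n",
                x$percent, as.integer(x$n_informative),
                100 * x$ci[1], 100 * x$ci[2], x$drive_call))
  }
  invisible(x)
}

#' Drive estimates for a whole pollen-FISH table
#'
#' @param table Data frame with columns `variant`, `total`, `none`,
#'   `vn_only`, `sn_only`, `all_nuclei`.
#' @param conf Confidence level passed to [drive_frequency()].
#' @return The input with columns `frequency`, `percent`, `ci_low`,
#'   `ci_high`, `drive_call` appended.
#' @export
drive_table <- function(table, conf = 0.95) {
  est <- lapply(seq_len(nrow(table)), function(i) {
    drive_frequency(as.list(table[i, , drop = FALSE]), conf = conf)
  })
  table$frequency <- vapply(est, `[[`, numeric(1), "frequency")
  table$percent <- vapply(est, `[[`, numeric(1), "percent")
  table$ci_low <- vapply(est, function(e) e$ci[1], numeric(1))
  table$ci_high <- vapply(est, function(e) e$ci[2], numeric(1))
  table$drive_call <- vapply(est, `[[`, character(1), "drive_call")
  table
}

#' Percentage from a printed count pair
#'
#' @param k Numerator count (successes).
#' @param n Denominator count; must be positive.
#' @param decimals Decimals for half-up rounding of the percentage.
#' @param conf Confidence level of the Wilson interval.
#' @return List with `percent` (rounded), `raw` (unrounded percent) and `ci`
#'   (Wilson interval on the proportion scale).
#' @examples
#' proportion(94, 336, 0)$percent  # 28
#' @export
proportion <- function(k, n, decimals = 1, conf = 0.95) {
  assert_scalar_number(k, "k"); assert_scalar_number(n, "n")
  if (n <= 0) stopf("proportion undefined for n = %g", n)
  if (k < 0 || k > n) stopf("k must lie in [0, n]")
  p <- k / n
  list(percent = round_half_up(100 * p, decimals),
       raw = 100 * p,
       ci = wilson_ci(k, n, conf = conf))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param conf Confidence level.
#' @return Numeric vector `c(low, high)` within `[0, 1]`, always containing
#'   `k/n`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  assert_scalar_number(k, "k"); assert_scalar_number(n, "n")
  if (n <= 0) stopf("wilson_ci undefined for n = %g", n)
  if (k < 0 || k > n) stopf("k must lie in [0, n]")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  low <- max(0, centre - half)
  high <- min(1, centre + half)
  c(low = low, high = high)
}

#' Read or write pollen-FISH tables
#'
#' TSV with columns `variant`, `total`, `none`, `vn_only`, `sn_only`,
#' `all_nuclei`.
#'
#' @param path File path.
#' @return `read_pollen_table` returns a data frame; `write_pollen_table`
#'   returns the path invisibly.
#' @export
read_pollen_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("variant", "total", "none", "vn_only", "sn_only", "all_nuclei")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L) {
    stopf("pollen table %s lacks columns: %s", path,
          paste(missing, collapse = ", "))
  }
  tab
}

#' @rdname read_pollen_table
#' @param table Data frame in the pollen-table schema.
#' @export
write_pollen_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
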