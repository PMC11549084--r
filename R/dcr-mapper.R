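#' Deletion mapping of the drive control region
#'
#' The drive control region (DCR) is delimited as the interval covered by
#' sequencing reads in every drive-positive karyotype line and devoid of
#' coverage in every drive-negative line. Windowed depth tracks per line are
#' reduced to a boolean presence matrix by a median-relative threshold
#' (robust to library-size differences between lines, so no cross-line
#' normalization is needed), differential windows are intersected across
#' lines, and runs of differential windows are merged across short
#' repeat-induced mapping dropouts.
#'
#' @name dcr-mapper
NULL

#' Aggregate a raw depth track into fixed windows
#'
#' @param raw Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `depth` (bedGraph-like), sorted by `start`; intervals
#'   must not overlap. Positions not covered by any interval count as depth
#'   0.
#' @param window Window size in bp (default 1 Mb).
#' @param chrom_length Chromosome length; defaults to the largest `end`.
#' @return A `coverage_track` data frame with per-window mean depth; the
#'   last window may be short and is normalized by its true length.
#' @export
window_depths <- function(raw, window = 1e6, chrom_length = NULL) {
  if (window < 1) stopf("window must be >= 1")
  if (nrow(raw) == 0) stopf("empty depth track")
  if (is.unsorted(raw$start)) stopf("raw track positions must be sorted")
  if (any(raw$end <= raw$start)) stopf("intervals must satisfy start < end")
  chrom_length <- chrom_length %||% max(raw$end)
  starts <- seq(0, chrom_length - 1, by = window)
  ends <- pmin(starts + window, chrom_length)
  base_sum <- numeric(length(starts))
  for (i in seq_len(nrow(raw))) {
    ov_lo <- pmax(starts, raw$start[i])
    ov_hi <- pmin(ends, raw$end[i])
    ov <- pmax(ov_hi - ov_lo, 0)
    base_sum <- base_sum + ov * raw$depth[i]
  }
  out <- data.frame(chrom = raw$chrom[1], start = starts, end = ends,
                    depth = base_sum / (ends - starts),
                    stringsAsFactors = FALSE)
  attr(out, "window") <- window
  class(out) <- c("coverage_track", "data.frame")
  out
}

#' Call per-window presence from a coverage track
#'
#' A window is called present iff its depth is at least `alpha` times the
#' per-line median depth over the chromosome.
#'
#' @param track A `coverage_track` data frame (columns `start`, `end`,
#'   `depth`).
#' @param alpha Fraction of the per-line median below which a window is
#'   absent.
#' @return Logical vector, one element per window, with attribute
#'   `median_depth`.
#' @export
call_presence <- function(track, alpha = 0.1) {
  if (nrow(track) == 0) stopf("empty coverage track")
  med <- median(track$depth)
  if (med == 0) {
    warnf("all-zero track: every window called absent")
    present <- rep(FALSE, nrow(track))
  } else if (alpha == 0) {
    present <- track$depth > 0
  } else {
    present <- track$depth >= alpha * med
  }
  attr(present, "median_depth") <- med
  present
}

#' Build a presence matrix from per-line coverage tracks
#'
#' @param tracks Named list of `coverage_track` data frames over identical
#'   windows.
#' @param alpha Passed to [call_presence()].
#' @return A list of class `presence_matrix`: logical matrix `present`
#'   (windows x lines), `windows` (data frame `chrom`, `start`, `end`),
#'   `medians` and `alpha`.
#' @export
presence_matrix <- function(tracks, alpha = 0.1) {
  if (is.null(names(tracks)) || any(names(tracks) == "")) {
    stopf("tracks must be a named list (line names)")
  }
  n_win <- vapply(tracks, nrow, integer(1))
  if (length(unique(n_win)) != 1) {
    stopf("tracks have inconsistent window counts: %s",
          paste(n_win, collapse = ", "))
  }
  cols <- lapply(tracks, call_presence, alpha = alpha)
  structure(list(
    present = do.call(cbind, lapply(cols, as.logical)),
    windows = tracks[[1]][, c("chrom", "start", "end")],
    medians = vapply(cols, attr, numeric(1), "median_depth"),
    alpha = alpha
  ), class = "presence_matrix")
}

#' Delimit differential intervals between line groups
#'
#' A window is differential iff present in all `positives` and absent in
#' all `negatives`. Runs of differential windows separated by at most
#' `merge_gap` non-differential windows are merged. The longest resulting
#' interval is flagged as the candidate DCR.
#'
#' @param matrix A `presence_matrix`.
#' @param positives,negatives Non-empty character vectors of line names.
#' @param merge_gap Maximum run of non-differential windows bridged when
#'   merging (default 2, to step over satellite-dense windows that map
#'   poorly in every line).
#' @return Data frame with columns `chrom`, `start`, `end` (bp, 0-based
#'   half-open), `start_1based` (1-based inclusive presentation
#'   coordinates), `n_windows`, `candidate` (logical; `TRUE` for the
#'   largest interval). Zero rows when no differential window exists.
#' @export
delimit_region <- function(matrix, positives, negatives, merge_gap = 2) {
  stopifnot(inherits(matrix, "presence_matrix"))
  if (length(positives) == 0 || length(negatives) == 0) {
    stopf("positives and negatives must be non-empty")
  }
  lines <- colnames(matrix$present)
  missing <- setdiff(c(positives, negatives), lines)
  if (length(missing) > 0) {
    stopf("unknown lines: %s", paste(missing, collapse = ", "))
  }
  pres <- matrix$present
  diff_win <- rowSums(pres[, positives, drop = FALSE]) == length(positives) &
    rowSums(pres[, negatives, drop = FALSE]) == 0
  if (!any(diff_win)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), start_1based = numeric(0),
                      n_windows = integer(0), candidate = logical(0)))
  }
  idx <- which(diff_win)
  breaks <- which(diff(idx) > merge_gap + 1)
  run_start <- idx[c(1, breaks + 1)]
  run_end <- idx[c(breaks, length(idx))]
  out <- data.frame(
    chrom = matrix$windows$chrom[run_start],
    start = matrix$windows$start[run_start],
    end = matrix$windows$end[run_end],
    stringsAsFactors = FALSE
  )
  out$start_1based <- out$start + 1
  out$n_windows <- run_end - run_start + 1L
  width <- out$end - out$start
  out$candidate <- seq_len(nrow(out)) == which.max(width)
  out[order(out$start), ]
}

#' Classify unplaced contigs as DCR-linked
#'
#' A contig is DCR-linked iff, by the whole-contig mean-depth rule, it is
#' present in all drive-positive lines and absent in all drive-negative
#' lines. Presence uses the same `alpha` x per-line-median threshold as
#' window calling, the median being taken over contigs within each line.
#'
#' @param contig_depths Data frame with columns `contig`, `line`,
#'   `mean_depth` (long format), or a numeric matrix contigs x lines.
#' @param positives,negatives Line names.
#' @param alpha Presence threshold as a fraction of the per-line median.
#' @return Data frame `contig`, `dcr_linked` (logical).
#' @export
classify_unplaced <- function(contig_depths, positives, negatives,
                              alpha = 0.1) {
  if (is.data.frame(contig_depths)) {
    ctg <- sort(unique(contig_depths$contig))
    lns <- unique(contig_depths$line)
    m <- matrix(NA_real_, length(ctg), length(lns),
                dimnames = list(ctg, lns))
    m[cbind(match(contig_depths$contig, ctg),
            match(contig_depths$line, lns))] <- contig_depths$mean_depth
  } else {
    m <- contig_depths
  }
  missing <- setdiff(c(positives, negatives), colnames(m))
  if (length(missing) > 0) {
    stopf("unknown lines: %s", paste(missing, collapse = ", "))
  }
  meds <- apply(m, 2, median, na.rm = TRUE)
  present <- sweep(m, 2, alpha * meds, `>=`)
  linked <- rowSums(present[, positives, drop = FALSE]) == length(positives) &
    rowSums(present[, negatives, drop = FALSE]) == 0
  data.frame(contig = rownames(m), dcr_linked = unname(linked),
             stringsAsFactors = FALSE)
}

#' Write differential intervals as BED plus a JSON report
#'
#' @param intervals Result of [delimit_region()].
#' @param matrix The `presence_matrix` used.
#' @param dir Output directory.
#' @param prefix File prefix.
#' @return Named vector of paths, invisibly.
#' @export
write_dcr_report <- function(intervals, matrix, dir, prefix = "dcr") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- file.path(dir, paste0(prefix, ".bed"))
  rep_path <- file.path(dir, paste0(prefix, "_report.json"))
  write.table(intervals[, c("chrom", "start", "end")], bed, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(
    alpha = matrix$alpha,
    medians = as.list(matrix$medians),
    window = matrix$windows$end[1] - matrix$windows$start[1],
    intervals = intervals
  ), rep_path, auto_unbox = TRUE, digits = NA)
  invisible(c(bed = bed, report = rep_path))
}
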