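#' Repeat-family assignment and assembly-completeness estimation
#'
#' Satellite arrays collapse during assembly, so the assembled bp of a
#' repeat family underestimates its genomic abundance. The completeness
#' estimator compares two populations of fixed-length (150 bp) sequences:
#' tiles cut from the assembly and unassembled reads representing exactly 1x
#' genome coverage. After removing host-matching sequences, both populations
#' are assigned to repeat families by exact k-mer containment, and the
#' assembled fraction of a family is
#'
#' \deqn{fraction = tiles\ matched / reads\ matched}
#'
#' With error-free reads at exactly 1x, each population counts 150-bp units
#' of the family, in the assembly and in the genome respectively.
#'
#' @name repeat-quant
NULL

kmer_set <- function(seq, k) {
  s <- as.character(seq)
  n <- nchar(s)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  unique(substring(s, starts, starts + k - 1L))
}

# k-mer sets of each family reference, both strands
library_kmers <- function(library, k) {
  lapply(seq_along(library), function(i) {
    fwd <- kmer_set(library[[i]], k)
    rev <- kmer_set(Biostrings::reverseComplement(library[[i]]), k)
    unique(c(fwd, rev))
  }) |> setNames(names(library))
}

# Fraction of each query's k-mers contained in a reference k-mer set,
# vectorized over queries (all queries must share one length).
query_kmer_fractions <- function(queries, ref_kmers, k) {
  qs <- as.character(queries)
  n <- nchar(qs[1])
  starts <- seq_len(n - k + 1L)
  hits <- vapply(starts, function(st) {
    data.table::`%chin%`(substring(qs, st, st + k - 1L), ref_kmers)
  }, logical(length(qs)))
  if (length(qs) == 1L) return(mean(hits))
  rowMeans(hits)
}

#' Assign fixed-length queries to repeat families by k-mer containment
#'
#' A query matches family `F` iff at least `min_kmer_frac` of its k-mers
#' occur in `F`'s reference sequence on either strand. When several
#' families qualify, the highest k-mer fraction wins; exact ties go to the
#' lexicographically first family and are reported.
#'
#' @param queries A [Biostrings::DNAStringSet] of equal-length sequences
#'   (length >= `k`).
#' @param library A named [Biostrings::DNAStringSet] of family reference
#'   sequences.
#' @param k K-mer length.
#' @param min_kmer_frac Minimum fraction of query k-mers contained in the
#'   reference.
#' @return A list of class `repeat_assignment`: `family` (character, `NA`
#'   for unassigned), `fraction` (winning k-mer fraction) and `ties`
#'   (indices of tied queries).
#' @export
match_repeats <- function(queries, library, k = 31, min_kmer_frac = 0.5) {
  if (length(queries) == 0) {
    return(structure(list(family = character(0), fraction = numeric(0),
                          ties = integer(0)), class = "repeat_assignment"))
  }
  if (any(Biostrings::width(queries) < k)) {
    stopf("k (%d) exceeds query length (%d)", k,
          min(Biostrings::width(queries)))
  }
  if (is.null(names(library)) || anyDuplicated(names(library))) {
    stopf("library must have unique family names")
  }
  fams <- sort(names(library))
  km <- library_kmers(library, k)
  frac <- vapply(fams, function(f) query_kmer_fractions(queries, km[[f]], k),
                 numeric(length(queries)))
  if (length(queries) == 1L) frac <- matrix(frac, nrow = 1,
                                            dimnames = list(NULL, fams))
  qualified <- frac >= min_kmer_frac
  best <- apply(frac, 1, which.max)
  assigned <- qualified[cbind(seq_along(best), best)]
  family <- ifelse(assigned, fams[best], NA_character_)
  n_best <- rowSums(qualified & frac == frac[cbind(seq_along(best), best)])
  ties <- which(assigned & n_best > 1)
  if (length(ties) > 0) {
    warnf("%d query/queries tied between families; lexicographically first kept",
          length(ties))
  }
  structure(list(family = family,
                 fraction = frac[cbind(seq_along(best), best)],
                 ties = ties),
            class = "repeat_assignment")
}

#' Remove queries matching the host genome
#'
#' Applies the same k-mer containment rule against the host sequence and
#' drops matching queries, emulating host-genome subtraction of reads
#' before repeat assignment.
#'
#' @param queries A [Biostrings::DNAStringSet].
#' @param host A [Biostrings::DNAString], character string, or
#'   [Biostrings::DNAStringSet] of host chromosomes.
#' @param k K-mer length.
#' @param min_kmer_frac Containment threshold.
#' @return The retained [Biostrings::DNAStringSet].
#' @export
host_subtract <- function(queries, host, k = 31, min_kmer_frac = 0.5) {
  if (length(queries) == 0) return(queries)
  if (is(host, "DNAStringSet")) {
    hk <- unique(unlist(library_kmers(host, k), use.names = FALSE))
  } else {
    host <- Biostrings::DNAString(as.character(host))
    hk <- unique(c(kmer_set(host, k),
                   kmer_set(Biostrings::reverseComplement(host), k)))
  }
  frac <- query_kmer_fractions(queries, hk, k)
  queries[frac < min_kmer_frac]
}

#' Windowed abundance track of annotated repeat families
#'
#' @param annotations Data frame with columns `chrom`, `family`, `start`,
#'   `end` (0-based half-open), sorted by start within chromosome.
#' @param window Window size in bp (default 1 Mb).
#' @param chrom_length Chromosome length; defaults to the largest feature
#'   end.
#' @return Data frame `chrom`, `start`, `end`, one column per family with
#'   annotated bp per window; features spanning a window boundary are split
#'   proportionally.
#' @export
abundance_track <- function(annotations, window = 1e6, chrom_length = NULL) {
  if (nrow(annotations) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  if (is.unsorted(annotations$start)) stopf("annotations must be sorted")
  chrom_length <- chrom_length %||% max(annotations$end)
  starts <- seq(0, chrom_length - 1, by = window)
  ends <- pmin(starts + window, chrom_length)
  fams <- sort(unique(annotations$family))
  out <- data.frame(chrom = annotations$chrom[1], start = starts, end = ends,
                    stringsAsFactors = FALSE)
  for (f in fams) {
    sel <- annotations$family == f
    bp <- numeric(length(starts))
    for (i in which(sel)) {
      ov <- pmax(pmin(ends, annotations$end[i]) -
                   pmax(starts, annotations$start[i]), 0)
      bp <- bp + ov
    }
    out[[f]] <- bp
  }
  out
}

#' Estimate per-family assembly completeness
#'
#' Tiles the assembly into `read_len`-bp sequences, removes host-matching
#' tiles and reads, assigns both populations to the repeat library, and
#' reports per family `tiles / reads`. When the read set does not represent
#' exactly 1x coverage of its source genome, supply `genome_size` and the
#' read counts are rescaled by the actual coverage
#' `total read bp / genome_size` (the factor is reported).
#'
#' @param assembly A [Biostrings::DNAStringSet] (or single sequence) of the
#'   assembly to evaluate.
#' @param reads A [Biostrings::DNAStringSet] of fixed-length reads drawn at
#'   ~1x from the source genome.
#' @param host Host genome sequence(s) for subtraction, or `NULL` to skip.
#' @param library Named [Biostrings::DNAStringSet] of repeat references.
#' @param k K-mer length.
#' @param min_kmer_frac Containment threshold.
#' @param genome_size Size in bp of the genome the reads were drawn from
#'   (for the 1x rescaling); `NULL` assumes exactly 1x.
#' @param read_len Read/tile length in bp.
#' @param exclude Families to leave out of the report (e.g. organellar or
#'   host-shared families for which the ratio is not interpretable).
#' @return A data frame of class `completeness_report` with columns
#'   `family`, `tiles`, `reads`, `fraction` (`NA` when `reads` is 0) and
#'   `se` (binomial standard error); attribute `coverage_factor` records the
#'   1x rescaling applied.
#' @export
completeness <- function(assembly, reads, host, library, k = 31,
                         min_kmer_frac = 0.5, genome_size = NULL,
                         read_len = 150, exclude = character(0)) {
  if (!is(assembly, "DNAStringSet")) {
    assembly <- Biostrings::DNAStringSet(as.character(assembly))
  }
  tiles <- tile_sequence(assembly, k = read_len)
  if (!all(Biostrings::width(reads) == read_len)) {
    stopf("reads must all be %d bp", read_len)
  }
  cov_factor <- 1
  if (!is.null(genome_size)) {
    cov_factor <- sum(as.numeric(Biostrings::width(reads))) / genome_size
  }
  if (!is.null(host)) {
    tiles <- host_subtract(tiles, host, k, min_kmer_frac)
    reads <- host_subtract(reads, host, k, min_kmer_frac)
  }
  fams <- setdiff(sort(names(library)), exclude)
  lib <- library[fams]
  tile_asg <- match_repeats(tiles, lib, k, min_kmer_frac)
  read_asg <- match_repeats(reads, lib, k, min_kmer_frac)
  tile_n <- table(factor(tile_asg$family, levels = fams))
  read_n <- table(factor(read_asg$family, levels = fams))
  reads_adj <- as.numeric(read_n) / cov_factor
  frac <- ifelse(reads_adj > 0, as.numeric(tile_n) / reads_adj, NA_real_)
  se <- ifelse(reads_adj > 0,
               sqrt(pmax(frac * (1 - pmin(frac, 1)), 0) / reads_adj),
               NA_real_)
  out <- data.frame(family = fams,
                    tiles = as.numeric(tile_n),
                    reads = reads_adj,
                    fraction = frac,
                    se = se,
                    stringsAsFactors = FALSE)
  attr(out, "coverage_factor") <- cov_factor
  class(out) <- c("completeness_report", "data.frame")
  out
}

#' Write a completeness report as TSV
#'
#' @param report A `completeness_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_completeness <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
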