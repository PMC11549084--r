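#' Subtractive differential-expression funnel
#'
#' Candidate drive genes are found by a staged subtractive funnel: at each
#' stage, one-sided negative-binomial tests compare drive-positive against
#' drive-negative genotype groups, genes upregulated (fold change > 2,
#' BH-adjusted p < 0.01) in *every* comparison of the stage are kept, and
#' stages intersect cumulatively. Surviving genes are clustered by sequence
#' similarity, filtered for DCR exclusivity by in-silico PCR against
#' drive-positive and drive-negative variant genomes, and profiled across
#' tissues (TPM) with an ORF-length coding rule.
#'
#' The DE statistic is implemented here in full (median-of-ratios
#' normalization, method-of-moments dispersion, delta-method Wald test) so
#' the package is self-contained; exact concordance with any packaged DE
#' method is not claimed — the correctness contract is calibration of the
#' test under the null and recovery of planted effects.
#'
#' @name dge-funnel
NULL

get_counts <- function(counts) {
  if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
}

#' Median-of-ratios size factors
#'
#' Reference = per-gene geometric mean over samples, computed on genes with
#' no zero count; each sample's factor is the median over those genes of
#' `count / reference`. When no gene is all-positive the factors fall back
#' to total-count ratios (normalized to geometric mean 1) with a warning.
#'
#' @param counts Integer matrix genes x samples, or a `count_matrix`.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  m <- get_counts(counts)
  usable <- rowSums(m == 0) == 0
  if (!any(usable)) {
    warnf("no gene with positive counts in every sample; using total-count factors")
    tot <- colSums(m)
    return(tot / exp(mean(log(tot))))
  }
  lm <- log(m[usable, , drop = FALSE])
  ref <- rowMeans(lm)
  apply(exp(lm - ref), 2, median)
}

#' One-sided negative-binomial Wald test between two groups
#'
#' Counts are normalized by [size_factors()] computed on the samples of the
#' two groups. Group means get a pseudocount of 0.5;
#' `log2fc = log2(m_pos / m_neg)`. NB dispersion is estimated by method
#' of moments on the normalized counts, floored at 1e-8: the default
#' `"pooled"` mode uses a ratio-form estimator across genes
#' (`sum(v - mu) / sum(mu^2)`), which is nearly unbiased at small replicate
#' numbers and keeps the Wald test calibrated; `"per-gene"` uses each
#' gene's own (noisier) estimate. The
#' standard error of `log2fc` follows from the delta method under the NB
#' variance `mu + dispersion * mu^2`, and the one-sided p-value is
#' `P(Z >= log2fc / se)` for upregulation in the positive group
#' (`alternative = "two-sided"` gives a two-sided p instead, to be combined
#' with a direction filter). BH adjustment is applied within the
#' comparison.
#'
#' @param counts A `count_matrix` or integer matrix (then `groups` must be
#'   given).
#' @param positive,negative Group labels to compare (>= 2 replicates each).
#' @param dispersion `"per-gene"` or `"pooled"`.
#' @param alternative `"greater"` (one-sided upregulation) or
#'   `"two-sided"`.
#' @param groups Named character vector sample -> group when `counts` is a
#'   bare matrix.
#' @return Data frame of class `de_result`: `gene`, `base_mean`, `log2fc`,
#'   `se`, `p`, `padj`.
#' @export
nb_test <- function(counts, positive, negative,
                    dispersion = c("pooled", "per-gene"),
                    alternative = c("greater", "two-sided"),
                    groups = NULL) {
  dispersion <- match.arg(dispersion)
  alternative <- match.arg(alternative)
  m <- get_counts(counts)
  if (inherits(counts, "count_matrix")) {
    groups <- setNames(counts$samples$group, counts$samples$sample)
  }
  if (is.null(groups)) stopf("groups must be supplied with a bare matrix")
  pos_s <- names(groups)[groups == positive]
  neg_s <- names(groups)[groups == negative]
  if (length(pos_s) < 2 || length(neg_s) < 2) {
    stopf("each group needs >= 2 replicates (got %d vs %d)",
          length(pos_s), length(neg_s))
  }
  sub <- m[, c(pos_s, neg_s), drop = FALSE]
  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, `/`)
  npos <- length(pos_s); nneg <- length(neg_s)
  mp_raw <- rowMeans(norm[, pos_s, drop = FALSE])
  mn_raw <- rowMeans(norm[, neg_s, drop = FALSE])
  vp <- apply(norm[, pos_s, drop = FALSE], 1, var)
  vn <- apply(norm[, neg_s, drop = FALSE], 1, var)

  if (dispersion == "pooled") {
    # ratio-form method of moments across genes: E[v - mu] = alpha * mu^2,
    # so alpha = sum(v - mu) / sum(mu^2); nearly unbiased even at n = 3,
    # unlike the median of per-gene estimates
    a <- (sum(vp - mp_raw, na.rm = TRUE) + sum(vn - mn_raw, na.rm = TRUE)) /
      (sum(mp_raw^2) + sum(mn_raw^2))
    alpha <- rep(max(a, 1e-8), length(mp_raw))
  } else {
    mom <- function(mu, v) ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
    alpha <- rowMeans(cbind(mom(mp_raw, vp), mom(mn_raw, vn)), na.rm = TRUE)
    alpha[is.nan(alpha) | is.na(alpha)] <- 0
    alpha <- pmax(alpha, 1e-8)
  }

  mp <- mp_raw + 0.5
  mn <- mn_raw + 0.5
  log2fc <- log2(mp / mn)
  se <- sqrt((1 / log(2)^2) *
               ((mp + alpha * mp^2) / (npos * mp^2) +
                  (mn + alpha * mn^2) / (nneg * mn^2)))
  z <- log2fc / se
  p <- if (alternative == "greater") 1 - pnorm(z) else 2 * pnorm(-abs(z))
  padj <- p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(m) %||% as.character(seq_len(nrow(m))),
                    base_mean = (mp_raw + mn_raw) / 2,
                    log2fc = log2fc, se = se, p = p, padj = padj,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Select upregulated genes from a DE result
#'
#' Strict inequalities, matching the "fold change > 2, adjusted p < 0.01"
#' rule: a gene passes iff `log2fc > lfc_min` *and* `padj < alpha`.
#'
#' @param results A `de_result` data frame.
#' @param lfc_min Minimum log2 fold change (exclusive).
#' @param alpha Maximum adjusted p-value (exclusive).
#' @return Character vector of gene ids.
#' @export
call_upregulated <- function(results, lfc_min = 1, alpha = 0.01) {
  results$gene[results$log2fc > lfc_min & results$padj < alpha]
}

#' Default funnel configuration (11 comparisons in 4 stages)
#'
#' Stage 1: wheat drive-positive groups (2Bs, 4Bs, 1Bk-2) each vs wheat 0B.
#' Stage 2: the same three vs wheat + 1Bs-8. Stage 3: the same three vs
#' wheat + 1Bk-1. Stage 4: rye 2B vs rye 0B and vs rye + 1defB.
#'
#' @param lfc_min,alpha Thresholds passed to [call_upregulated()].
#' @return List of class `funnel_config` with `stages` (list of lists of
#'   `c(positive, negative)` pairs), `lfc_min`, `alpha`.
#' @export
default_funnel_config <- function(lfc_min = 1, alpha = 0.01) {
  wheat_pos <- c("wheat_2Bs", "wheat_4Bs", "wheat_1Bk2")
  stages <- list(
    lapply(wheat_pos, function(g) c(g, "wheat_0B")),
    lapply(wheat_pos, function(g) c(g, "wheat_1Bs8")),
    lapply(wheat_pos, function(g) c(g, "wheat_1Bk1")),
    list(c("rye_2B", "rye_0B"), c("rye_2B", "rye_1defB"))
  )
  structure(list(stages = stages, lfc_min = lfc_min, alpha = alpha),
            class = "funnel_config")
}

#' Run the staged subtractive DE funnel
#'
#' Each stage's gene set is the intersection of [call_upregulated()] over
#' all its comparisons, intersected with the previous stage's set. An empty
#' intermediate set does not stop the pipeline; downstream sets are simply
#' empty.
#'
#' @param counts A `count_matrix` containing every group referenced by the
#'   config.
#' @param config A `funnel_config`.
#' @param dispersion,alternative Passed to [nb_test()].
#' @return List of class `funnel_result`: `stage_sets` (list of character
#'   vectors), `stage_counts`, `final` (last stage's set), and
#'   `comparisons` (per-comparison upregulated-set sizes).
#' @export
run_funnel <- function(counts, config = default_funnel_config(),
                       dispersion = "pooled", alternative = "greater") {
  stopifnot(inherits(config, "funnel_config"))
  groups <- unique(counts$samples$group)
  referenced <- unique(unlist(config$stages))
  missing <- setdiff(referenced, groups)
  if (length(missing) > 0) {
    stopf("config references unknown groups: %s",
          paste(missing, collapse = ", "))
  }
  current <- NULL
  stage_sets <- list()
  comp_log <- list()
  for (s in seq_along(config$stages)) {
    sets <- lapply(config$stages[[s]], function(cmp) {
      res <- nb_test(counts, cmp[1], cmp[2], dispersion = dispersion,
                     alternative = alternative)
      up <- call_upregulated(res, config$lfc_min, config$alpha)
      comp_log[[paste(cmp, collapse = "_vs_")]] <<- length(up)
      up
    })
    stage_set <- Reduce(intersect, sets)
    if (!is.null(current)) stage_set <- intersect(current, stage_set)
    current <- stage_set
    stage_sets[[s]] <- stage_set
  }
  structure(list(stage_sets = stage_sets,
                 stage_counts = vapply(stage_sets, length, integer(1)),
                 final = current,
                 comparisons = comp_log),
            class = "funnel_result")
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("subtractive DE funnel:", paste(x$stage_counts, collapse = " -> "),
      "genes\n")
  invisible(x)
}

#' Greedy incremental sequence clustering
#'
#' CD-HIT-style clustering: sequences are sorted by decreasing length (ties
#' by name); each sequence joins the first existing cluster whose
#' representative it matches at the identity threshold, otherwise it founds
#' a new cluster. Identity is matched bases of an end-gap-free (overlap)
#' alignment divided by the shorter sequence length, taking the better of
#' the two strands.
#'
#' @param sequences A named [Biostrings::DNAStringSet].
#' @param identity Identity threshold in `(0, 1]`.
#' @return List of class `seq_clusters`: `cluster` (named integer vector),
#'   `representatives` (character vector of sequence names, one per
#'   cluster).
#' @export
cluster_sequences <- function(sequences, identity = 0.8) {
  if (length(sequences) == 0) stopf("need at least one sequence")
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  ord <- order(-Biostrings::width(sequences), names(sequences))
  seqs <- sequences[ord]
  reps <- integer(0)
  cluster <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    assigned <- FALSE
    for (ci in seq_along(reps)) {
      if (pair_identity(seqs[[i]], seqs[[reps[ci]]]) >= identity) {
        cluster[i] <- ci
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }
  structure(list(cluster = setNames(cluster, names(seqs)),
                 representatives = names(seqs)[reps]),
            class = "seq_clusters")
}

#' Pairwise identity under an end-gap-free alignment
#'
#' @param a,b Sequences ([Biostrings::DNAString] or character).
#' @return Matched bases / shorter sequence length, best of both strands.
#' @export
pair_identity <- function(a, b) {
  a <- Biostrings::DNAString(as.character(a))
  b <- Biostrings::DNAString(as.character(b))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln_id <- function(x) {
    aln <- Biostrings::pairwiseAlignment(
      x, b, type = "overlap", substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 1)
    Biostrings::nmatch(aln)
  }
  best <- max(aln_id(a), aln_id(Biostrings::reverseComplement(a)))
  best / min(length(a), length(b))
}

#' In-silico PCR with exact primer matching
#'
#' Finds amplicons wherever the forward primer matches exactly and the
#' reverse complement of the reverse primer matches exactly downstream
#' within `max_product` bp; both template orientations are scanned.
#' Amplicon length runs from the 5' end of one primer site to the 3' end of
#' the other, inclusive.
#'
#' @param genome A [Biostrings::DNAStringSet], `DNAString`, character
#'   vector, or `genome_model`.
#' @param forward,reverse Primer sequences (>= 15 nt, plain ACGT only).
#' @param max_product Maximum amplicon length in bp.
#' @return Data frame `seqname`, `start`, `end` (1-based inclusive),
#'   `length`, `orientation` (`"+"` if the forward primer sits on the plus
#'   strand).
#' @export
insilico_pcr <- function(genome, forward, reverse, max_product = 5000) {
  if (inherits(genome, "genome_model")) genome <- genome$seqs
  if (!is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(as.character(genome))
    if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  }
  for (p in c(forward, reverse)) {
    if (nchar(p) < 15) stopf("primers must be >= 15 nt")
    if (grepl("[^ACGTacgt]", p)) {
      stopf("degenerate or non-ACGT base in primer '%s': exact matching only", p)
    }
  }
  fwd <- Biostrings::DNAString(toupper(forward))
  rev <- Biostrings::DNAString(toupper(reverse))
  rc_rev <- Biostrings::reverseComplement(rev)
  rc_fwd <- Biostrings::reverseComplement(fwd)
  hits <- list()
  scan <- function(subj, left, right, orientation, seqname) {
    ls <- Biostrings::start(Biostrings::matchPattern(left, subj))
    re <- Biostrings::end(Biostrings::matchPattern(right, subj))
    for (s in ls) {
      ok <- re[re >= s + length(left) + length(right) - 1 &
                 re - s + 1 <= max_product]
      for (e in ok) {
        hits[[length(hits) + 1L]] <<- data.frame(
          seqname = seqname, start = s, end = e, length = e - s + 1,
          orientation = orientation, stringsAsFactors = FALSE)
      }
    }
  }
  for (i in seq_along(genome)) {
    nm <- names(genome)[i] %||% paste0("seq", i)
    scan(genome[[i]], fwd, rc_rev, "+", nm)
    scan(genome[[i]], rev, rc_fwd, "-", nm)
  }
  if (length(hits) == 0) {
    return(data.frame(seqname = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      orientation = character(0)))
  }
  do.call(rbind, hits)
}

#' DCR-exclusivity filter by in-silico PCR
#'
#' A gene is retained iff its primer pair yields at least one amplicon in
#' *every* drive-positive genome and in *none* of the drive-negative
#' genomes — the signature of a gene whose copies all lie inside the DCR.
#'
#' @param primers Data frame with columns `gene`, `fwd`, `rev`.
#' @param positive_genomes,negative_genomes Lists of genomes (each a
#'   `genome_model` or [Biostrings::DNAStringSet]).
#' @param max_product Passed to [insilico_pcr()].
#' @return Data frame `gene`, `in_all_positives`, `in_any_negative`,
#'   `retained`.
#' @export
exclusivity_filter <- function(primers, positive_genomes, negative_genomes,
                               max_product = 5000) {
  amp <- function(genome, fwd, rev) {
    nrow(insilico_pcr(genome, fwd, rev, max_product)) > 0
  }
  res <- lapply(seq_len(nrow(primers)), function(i) {
    fwd <- primers$fwd[i]; rev <- primers$rev[i]
    in_pos <- vapply(positive_genomes, amp, logical(1), fwd = fwd, rev = rev)
    in_neg <- vapply(negative_genomes, amp, logical(1), fwd = fwd, rev = rev)
    data.frame(gene = primers$gene[i],
               in_all_positives = all(in_pos),
               in_any_negative = any(in_neg),
               retained = all(in_pos) && !any(in_neg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Transcripts-per-million normalization
#'
#' `rate = count / (length / 1000)`; each sample's rates are scaled to sum
#' to one million.
#'
#' @param counts Matrix genes x samples or `count_matrix`.
#' @param gene_lengths Named (or positionally matched) vector of gene
#'   lengths in bp, all positive.
#' @return Numeric matrix of TPM values; all-zero samples give all-zero
#'   columns with a warning.
#' @export
compute_tpm <- function(counts, gene_lengths) {
  m <- get_counts(counts)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(m))) {
    gene_lengths <- gene_lengths[rownames(m)]
  }
  if (any(is.na(gene_lengths)) || any(gene_lengths <= 0)) {
    stopf("gene lengths must be positive for every gene")
  }
  rate <- m / (gene_lengths / 1000)
  tot <- colSums(rate)
  if (any(tot == 0)) warnf("all-zero sample(s): TPM column left at zero")
  tpm <- sweep(rate, 2, ifelse(tot == 0, 1, tot), `/`) * 1e6
  tpm[, tot == 0] <- 0
  tpm
}

#' Longest open reading frame over six frames
#'
#' Scans all six reading frames for the longest ATG-to-stop ORF under the
#' standard genetic code; codons containing N are treated as translatable
#' unknowns (they neither start nor stop an ORF). The coding flag requires
#' a peptide strictly longer than 100 residues.
#'
#' @param transcript Nucleotide sequence (character or
#'   [Biostrings::DNAString]) over A, C, G, T, N.
#' @param min_aa Coding threshold in residues (exclusive).
#' @return List with `aa_length` (longest ORF peptide length, 0 if none)
#'   and `coding` (logical).
#' @export
find_longest_orf <- function(transcript, min_aa = 100) {
  s <- toupper(as.character(transcript))
  if (grepl("[^ACGTN]", s)) stopf("transcript must be over A, C, G, T, N")
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (strand_seq in c(s, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s))))) {
    n <- nchar(strand_seq)
    for (off in 0:2) {
      n_codons <- (n - off) %/% 3
      if (n_codons == 0) next
      starts <- off + 1L + 3L * (seq_len(n_codons) - 1L)
      codons <- substring(strand_seq, starts, starts + 2L)
      atg_open <- NA_integer_
      for (ci in seq_len(n_codons)) {
        cd <- codons[ci]
        if (cd %in% stops) {
          if (!is.na(atg_open)) {
            best <- max(best, ci - atg_open)
            atg_open <- NA_integer_
          }
        } else if (is.na(atg_open) && cd == "ATG") {
          atg_open <- ci
        }
      }
    }
  }
  list(aa_length = as.integer(best), coding = best > min_aa)
}

#' Rank candidates by first-pollen-mitosis specificity
#'
#' @param tpm Numeric matrix genes x tissues.
#' @param pmi_col Name of the PMI tissue column.
#' @return Data frame `gene`, `pmi_tpm`, `ratio`
#'   (`PMI / max(other tissues)`; `Inf` for genes expressed only at PMI),
#'   sorted by `pmi_tpm` descending.
#' @export
pmi_specificity <- function(tpm, pmi_col = "PMI") {
  if (!(pmi_col %in% colnames(tpm))) {
    stopf("PMI column '%s' not present", pmi_col)
  }
  others <- tpm[, setdiff(colnames(tpm), pmi_col), drop = FALSE]
  max_other <- apply(others, 1, max)
  pmi <- tpm[, pmi_col]
  ratio <- ifelse(max_other > 0, pmi / max_other,
                  ifelse(pmi > 0, Inf, NA_real_))
  out <- data.frame(gene = rownames(tpm) %||% as.character(seq_len(nrow(tpm))),
                    pmi_tpm = pmi, ratio = ratio,
                    stringsAsFactors = FALSE)
  out[order(-out$pmi_tpm), ]
}
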