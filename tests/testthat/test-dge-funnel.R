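test_that("size factors match a brute-force median-of-ratios recomputation", {
  set.seed(2)
  m <- matrix(rnbinom(600, mu = 50, size = 20), 100, 6,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  sf <- size_factors(m)
  # direct oracle
  usable <- apply(m, 1, function(r) all(r > 0))
  ref <- exp(rowMeans(log(m[usable, ])))
  oracle <- apply(m[usable, ] / ref, 2, median)
  expect_equal(unname(sf), unname(oracle))

  # identical samples -> all factors 1
  same <- matrix(rep(c(3, 10, 50), 4), 3, 4)
  expect_true(all(size_factors(same) == 1))
  # doubling one sample doubles its factor
  m2 <- m; m2[, 3] <- m2[, 3] * 2
  sf2 <- size_factors(m2)
  expect_equal(unname(sf2[3] / sf2[1]), unname(2 * sf[3] / sf[1]),
               tolerance = 1e-10)
  # all-zero-containing genes trigger the fallback
  z <- m; z[cbind(1:100, rep(1:6, length.out = 100))] <- 0
  expect_warning(size_factors(z), "total-count")
})

test_that("the NB test handles degenerate and boundary inputs", {
  m <- rbind(allzero = c(0, 0, 0, 0),
             flat = c(10, 10, 10, 10),
             up = c(40, 38, 10, 11))
  colnames(m) <- paste0("s", 1:4)
  groups <- setNames(rep(c("a", "b"), each = 2), colnames(m))
  res <- nb_test(m, "a", "b", groups = groups)
  expect_equal(res$log2fc[res$gene == "allzero"], 0)
  expect_equal(res$p[res$gene == "allzero"], 0.5)
  expect_true(all(res$padj >= res$p))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_error(nb_test(m, "a", "b", groups = setNames(c("a", "b", "b", "b"),
                                                      colnames(m))),
               "replicates")
})

test_that("the one-sided test is calibrated under a permuted null", {
  typeI <- vapply(1:20, function(s) {
    cm <- simulate_counts(n_genes = 1000, design = null_design(),
                          planted = character(0), lfc = 0,
                          dispersion = 0.05, seed = s,
                          positive_groups = "g1")
    mean(nb_test(cm, "g1", "g2")$p < 0.05)
  }, numeric(1))
  expect_gte(mean(typeI), 0.03)
  expect_lte(mean(typeI), 0.07)
})

test_that("planted four-fold effects are estimated near their true fold change", {
  cm <- simulate_counts(n_genes = 800, design = null_design(),
                        planted = 40, lfc = 2, dispersion = 0.05,
                        seed = 7, positive_groups = "g1")
  res <- nb_test(cm, "g1", "g2")
  fc <- 2^res$log2fc[res$gene %in% cm$truth$planted]
  expect_gt(median(fc), 3)
  expect_lt(median(fc), 5.3)
})

test_that("BH adjustment within the comparison has the standard monotonicity properties", {
  cm <- simulate_counts(n_genes = 500, design = null_design(),
                        planted = 20, lfc = 2, seed = 5,
                        positive_groups = "g1")
  res <- nb_test(cm, "g1", "g2")
  o <- order(res$p)
  expect_true(all(diff(res$padj[o]) >= -1e-12))
  expect_gte(min(res$padj), min(res$p))
  expect_equal(res$padj, p.adjust(res$p, "BH"))
})

test_that("upregulation calls use strict inequalities at both thresholds", {
  res <- structure(data.frame(
    gene = c("at_lfc", "above", "at_alpha", "hit"),
    log2fc = c(1, 1.5, 2, 2), se = 0.1,
    p = c(1e-5, 1e-5, 0.005, 1e-5),
    padj = c(1e-4, 1e-4, 0.01, 1e-4)), class = c("de_result", "data.frame"))
  expect_equal(call_upregulated(res, lfc_min = 1, alpha = 0.01),
               c("above", "hit"))
})

test_that("the 11-comparison funnel recovers exactly the planted drive genes", {
  cm <- simulate_counts(n_genes = 2000, planted = 23, lfc = 2,
                        dispersion = 0.05, seed = 11)
  config <- default_funnel_config()
  expect_equal(sum(lengths(config$stages)), 11)
  fr <- run_funnel(cm, config)
  expect_setequal(fr$final, cm$truth$planted)
  # nesting: every stage is a subset of the previous
  for (s in 2:length(fr$stage_sets)) {
    expect_true(all(fr$stage_sets[[s]] %in% fr$stage_sets[[s - 1]]))
  }
})

test_that("null data funnels to empty sets at every stage", {
  cm <- simulate_counts(n_genes = 500, planted = character(0), lfc = 0,
                        seed = 3)
  fr <- run_funnel(cm)
  expect_true(all(fr$stage_counts == 0))
  expect_length(fr$final, 0)
})

test_that("greedy clustering matches all-pairs single-link clustering on mutated families", {
  set.seed(19)
  fams <- replicate(3, random_seq(400))
  seqs <- Biostrings::DNAStringSet(setNames(
    unlist(lapply(fams, function(f) c(f, mutate_seq(f, 0.05),
                                      mutate_seq(f, 0.08),
                                      mutate_seq(f, 0.1)))),
    sprintf("s%02d", 1:12)))
  cl <- cluster_sequences(seqs, identity = 0.8)
  expect_length(cl$representatives, 3)

  # all-pairs single-link oracle
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    adj[i, j] <- adj[j, i] <- pair_identity(seqs[[i]], seqs[[j]]) >= 0.8
  }
  diag(adj) <- TRUE
  comp <- rep(0L, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      frontier <- i
      while (length(frontier) > 0) {
        comp[frontier] <- cid
        frontier <- setdiff(which(rowSums(adj[, frontier, drop = FALSE]) > 0 &
                                    comp == 0L), frontier)
      }
    }
  }
  oracle_part <- split(names(seqs), comp[match(names(seqs), names(seqs))])
  got_part <- split(names(cl$cluster), cl$cluster)
  normalize <- function(p) unname(lapply(p, sort))[order(vapply(p, min, ""))]
  expect_equal(normalize(got_part), normalize(oracle_part))
})

test_that("identical sequences form one cluster and unrelated ones stay singletons", {
  same <- Biostrings::DNAStringSet(setNames(rep(random_seq(200), 5),
                                            paste0("a", 1:5)))
  expect_length(cluster_sequences(same)$representatives, 1)
  set.seed(23)
  diff_seqs <- Biostrings::DNAStringSet(setNames(replicate(10, random_seq(200)),
                                                 paste0("b", 1:10)))
  expect_length(cluster_sequences(diff_seqs)$representatives, 10)
  # reverse-complement sequences cluster together (strand symmetry)
  rc <- Biostrings::reverseComplement(same[1])
  names(rc) <- "rc"
  expect_length(cluster_sequences(c(same[1], rc))$representatives, 1)
})

test_that("in-silico PCR finds constructed amplicons and nothing spurious", {
  set.seed(29)
  tmpl <- random_seq(3000)
  fwd <- substr(tmpl, 1001, 1020)
  rev3 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(tmpl, 1481, 1500))))
  amp <- insilico_pcr(tmpl, fwd, rev3)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length, 500)
  expect_equal(amp$start, 1001)
  expect_equal(amp$end, 1500)

  # absent forward primer -> no amplicon
  expect_equal(nrow(insilico_pcr(tmpl, random_seq(20), rev3)), 0)
  # primer validation
  expect_error(insilico_pcr(tmpl, "ACGTACGTACGT", rev3), ">= 15")
  expect_error(insilico_pcr(tmpl, paste0(substr(fwd, 1, 19), "N"), rev3),
               "degenerate|non-ACGT")
  # swapped primer roles find the same product on the other orientation
  amp2 <- insilico_pcr(tmpl, rev3, fwd)
  expect_equal(amp2$length, 500)
  expect_equal(amp2$orientation, "-")
  # product-size ceiling
  far_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(tmpl, 2901, 2920))))
  expect_equal(nrow(insilico_pcr(tmpl, fwd, far_rev, max_product = 1000)), 0)
})

test_that("random 20-nt primers never amplify from randomized genomes", {
  set.seed(37)
  for (i in 1:20) {
    g <- random_seq(20000)
    expect_equal(nrow(insilico_pcr(g, random_seq(20), random_seq(20))), 0)
  }
})

test_that("the exclusivity filter keeps genes amplifying only in drive-positive variants", {
  g <- small_genome()
  b_len <- g$chromosomes$length[2]
  dcr <- g$truth$dcr_interval
  positives <- list(
    derive_variant(g, list(name = "Bs", deleted = NULL)),
    derive_variant(g, list(name = "Bk2", deleted = c(0.97 * b_len, b_len))))
  negatives <- list(
    derive_variant(g, list(name = "Bk3", deleted = c(dcr[1] - 1e4, b_len))))

  genes <- g$features[g$features$kind == "gene", ]
  in_dcr <- genes$start >= dcr[1] & genes$end <= dcr[2]
  pick <- c(head(which(in_dcr), 5), head(which(!in_dcr & genes$end < dcr[1] - 2e4), 4))
  primers <- do.call(rbind, lapply(pick, function(i) {
    s <- as.character(Biostrings::subseq(g$seqs[["chrB"]],
                                         genes$start[i] + 1, genes$end[i]))
    data.frame(gene = genes$family_or_id[i],
               fwd = substr(s, 1, 20),
               rev = as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(s, 481, 500)))),
               stringsAsFactors = FALSE)
  }))
  res <- exclusivity_filter(primers, positives, negatives)
  expect_equal(res$retained, rep(c(TRUE, FALSE), c(5, 4)))

  # a second copy outside the DCR disqualifies a gene
  dup_gene <- primers[1, ]
  amp_seq <- as.character(Biostrings::subseq(
    g$seqs[["chrB"]],
    genes$start[pick[1]] + 1, genes$start[pick[1]] + 500))
  dup_genomes_pos <- lapply(positives, function(v) v$seqs)
  dup_genomes_neg <- lapply(negatives, function(v) {
    c(v$seqs, Biostrings::DNAStringSet(c(extra_copy = amp_seq)))
  })
  res2 <- exclusivity_filter(dup_gene, dup_genomes_pos, dup_genomes_neg)
  expect_false(res2$retained)
})

test_that("TPM matches the closed form and columns sum to one million", {
  m <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- compute_tpm(m, c(a = 1000, b = 2000))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  single <- compute_tpm(matrix(5, 1, 1, dimnames = list("g", "s")), c(g = 500))
  expect_equal(unname(single[1, 1]), 1e6)
  set.seed(3)
  rnd <- matrix(rpois(60, 30), 10, 6,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  tpm_r <- compute_tpm(rnd, setNames(sample(500:3000, 10), paste0("g", 1:10)))
  expect_true(all(abs(colSums(tpm_r) - 1e6) < 1e-3))
  zero <- rnd; zero[, 2] <- 0
  expect_warning(tz <- compute_tpm(zero, setNames(rep(1000, 10),
                                                  paste0("g", 1:10))),
                 "all-zero")
  expect_true(all(tz[, 2] == 0))
})

test_that("six-frame ORF scanning matches a brute-force oracle on random transcripts", {
  # brute force: regex over every frame of both strands
  brute_orf <- function(s) {
    best <- 0L
    for (str_seq in c(s, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s))))) {
      for (off in 0:2) {
        codons <- substring(str_seq,
                            seq(off + 1, nchar(str_seq) - 2, 3),
                            seq(off + 3, nchar(str_seq), 3))
        open <- NA
        for (i in seq_along(codons)) {
          if (codons[i] %in% c("TAA", "TAG", "TGA")) {
            if (!is.na(open)) best <- max(best, i - open)
            open <- NA
          } else if (is.na(open) && codons[i] == "ATG") open <- i
        }
      }
    }
    best
  }
  set.seed(41)
  for (i in 1:15) {
    s <- random_seq(2000)
    expect_equal(find_longest_orf(s)$aa_length, brute_orf(s))
  }
})

test_that("ORF boundary cases follow the strict > 100 aa coding rule", {
  expect_equal(find_longest_orf("CCCCCCCCCCCC")$aa_length, 0)
  expect_false(find_longest_orf("CCCCCCCCCCCC")$coding)
  orf100 <- paste0("ATG", strrep("GCT", 99), "TAA")
  r <- find_longest_orf(orf100)
  expect_equal(r$aa_length, 100)
  expect_false(r$coding)
  orf101 <- paste0("ATG", strrep("GCT", 100), "TAA")
  expect_true(find_longest_orf(orf101)$coding)
  # ATG without a downstream stop is not an ORF
  expect_equal(find_longest_orf(paste0("ATG", strrep("GCA", 30)))$aa_length, 0)
})

test_that("PMI-specific genes rank first in the specificity profile", {
  set.seed(43)
  tpm <- matrix(runif(500, 1, 50), 100, 5,
                dimnames = list(sprintf("g%03d", 1:100),
                                c("root", "leaf", "spike", "PMII", "PMI")))
  tpm["g007", ] <- c(0, 0, 0, 0, 400)   # expressed only at PMI
  tpm["g008", ] <- rep(30, 5)           # flat
  rk <- pmi_specificity(tpm, pmi_col = "PMI")
  expect_equal(rk$gene[1], "g007")
  expect_true(is.infinite(rk$ratio[rk$gene == "g007"]))
  expect_equal(rk$ratio[rk$gene == "g008"], 1)
})

test_that("per-comparison results broadly agree with an independent DE implementation", {
  skip_if_not_installed("DESeq2")
  suppressMessages(requireNamespace("DESeq2"))
  cm <- simulate_counts(n_genes = 400, design = null_design(),
                        planted = 20, lfc = 2, dispersion = 0.05,
                        seed = 13, positive_groups = "g1")
  res <- nb_test(cm, "g1", "g2")
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      cm$counts, S4Vectors::DataFrame(condition = factor(cm$samples$group,
                                                         levels = c("g2", "g1"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- as.data.frame(DESeq2::results(dds))
  })
  # size factors agree (same median-of-ratios definition)
  expect_equal(unname(size_factors(cm$counts)),
               unname(DESeq2::sizeFactors(dds)), tolerance = 1e-6)
  # estimated fold changes strongly correlated for well-expressed genes
  keep <- res$base_mean > 20
  expect_gt(cor(res$log2fc[keep], ref$log2FoldChange[keep]), 0.95)
  # planted genes are significant in both
  planted <- res$gene %in% cm$truth$planted
  expect_true(all(res$padj[planted] < 0.01))
  expect_true(all(ref$padj[planted] < 0.01, na.rm = TRUE))
})
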