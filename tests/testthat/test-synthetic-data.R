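test_that("genome build is deterministic and respects the declared layout", {
  g1 <- build_genome(genome_spec(), seed = 7)
  g2 <- build_genome(genome_spec(), seed = 7)
  expect_identical(as.character(g1$seqs), as.character(g2$seqs))
  expect_identical(g1$features, g2$features)
  # sequence length equals declared length
  expect_equal(unname(Biostrings::width(g1$seqs)), g1$chromosomes$length)
  # features lie within their chromosome
  len <- setNames(g1$chromosomes$length, g1$chromosomes$name)
  expect_true(all(g1$features$start >= 0))
  expect_true(all(g1$features$end <= len[g1$features$chrom]))
  # no two features overlap (arrays and genes are placed disjointly)
  f <- g1$features[g1$features$chrom == "chrB", ]
  f <- f[order(f$start), ]
  expect_true(all(f$start[-1] >= f$end[-nrow(f)]))
})

test_that("repeat zones follow the model order, distal long arm ending in Sc9c130", {
  g <- small_genome()
  f <- g$features[g$features$kind == "repeat-array", ]
  centroid <- tapply((f$start + f$end) / 2, f$family_or_id, mean)
  expect_true(centroid["Bilby"] < centroid["CL11"])
  expect_true(centroid["CL11"] < centroid["D1100"])
  expect_true(centroid["D1100"] < centroid["Sc26c38"])
  expect_true(centroid["Sc26c38"] < centroid["E3900"])
  expect_true(centroid["E3900"] < centroid["Sc9c130"])
  expect_equal(unname(which.max(centroid)),
               which(names(centroid) == "Sc9c130"))
})

test_that("requested family fractions are realized within 1 percent of B length", {
  g <- small_genome()
  f <- g$features[g$features$kind == "repeat-array", ]
  b_len <- g$chromosomes$length[g$chromosomes$role == "B"]
  fams <- default_repeat_families()
  for (i in seq_len(nrow(fams))) {
    sel <- f$family_or_id == fams$family[i]
    realized <- sum(f$end[sel] - f$start[sel]) / b_len
    expect_lt(abs(realized - fams$fraction[i]), 0.01)
  }
})

test_that("zero repeat families yields a background-plus-genes genome", {
  spec <- genome_spec(repeat_families = default_repeat_families()[0, ],
                      host_length = 5e4, b_length = 1e5, n_genes = 5,
                      n_drive_genes = 2)
  g <- build_genome(spec, seed = 3)
  expect_true(all(g$features$kind == "gene"))
  expect_length(g$truth$planted_drive_genes, 2)
})

test_that("over-filled repeat zones are rejected naming the zone", {
  fams <- default_repeat_families()
  fams$fraction[fams$family == "E3900"] <- 0.2  # zone 0.90-0.96 holds 0.06
  expect_error(genome_spec(repeat_families = fams), "zone \\[0.9, 0.96\\]")
})

test_that("variant derivation removes exactly the deleted bases and shifts features", {
  g <- small_genome()
  b_len <- g$chromosomes$length[2]

  ident <- derive_variant(g, list(name = "same", deleted = NULL))
  expect_identical(as.character(ident$seqs[["chrB"]]),
                   as.character(g$seqs[["chrB"]]))
  expect_true(ident$variant$drive_positive)

  tip <- derive_variant(g, list(name = "tip", deleted = c(b_len - 1e4, b_len)))
  expect_equal(tip$chromosomes$length[2], b_len - 1e4)
  expect_equal(length(tip$seqs[["chrB"]]), b_len - 1e4)
  # retained prefix is untouched
  expect_identical(
    as.character(Biostrings::subseq(tip$seqs[["chrB"]], 1, b_len - 1e4)),
    as.character(Biostrings::subseq(g$seqs[["chrB"]], 1, b_len - 1e4)))

  expect_error(derive_variant(g, list(name = "bad", deleted = c(0, b_len + 1))),
               "chrB")
})

test_that("an internal gap in the D1100 zone leaves flanking D1100 arrays around it", {
  g <- small_genome()
  f <- g$features[g$features$family_or_id == "D1100", ]
  # delete the middle array plus everything distal of the E3900 zone
  mid <- f[order(f$start), ][2, ]
  v <- derive_variant(g, list(
    name = "Bk3like",
    deleted = rbind(c(mid$start, mid$end),
                    c(0.9 * g$chromosomes$length[2],
                      g$chromosomes$length[2]))))
  expect_false(v$variant$drive_positive)
  fd <- v$features[v$features$family_or_id == "D1100", ]
  expect_gte(nrow(fd), 2)  # arrays remain on both sides of the gap
  removed <- (mid$end - mid$start) + 0.1 * g$chromosomes$length[2]
  expect_equal(v$chromosomes$length[2], g$chromosomes$length[2] - removed)
})

test_that("contig depth simulation matches its negative-binomial moments", {
  contigs <- data.frame(contig = sprintf("c%04d", 1:1000), length = 1e5)
  d0 <- simulate_contig_depths(contigs, multiplicity = 2, base_depth = 10,
                               dispersion = 0, seed = 1)
  expect_true(all(d0$mean_depth == 20))

  d <- simulate_contig_depths(contigs, multiplicity = 3.14, base_depth = 14,
                              dispersion = 0.05, seed = 5)
  mu <- 14 * 3.14
  se <- sqrt(0.05) * mu / sqrt(1000)
  expect_lt(abs(mean(d$mean_depth) - mu), 3 * se)
  expect_error(simulate_contig_depths(contigs, dispersion = -1), "dispersion")
  expect_error(simulate_contig_depths(contigs, multiplicity = 0.5),
               "multiplicity")
})

test_that("window depth tracks zero out deleted windows and fluctuate elsewhere", {
  g <- small_genome()
  v <- derive_variant(g, list(name = "del", deleted = c(1e5, 5e5)))
  tr <- simulate_window_depths(v, window = 1e4, base_depth = 2, seed = 2)
  med <- median(tr$depth)
  deleted <- tr$start >= 1e5 & tr$end <= 5e5
  expect_true(all(tr$depth[deleted] < 0.05 * med))
  expect_true(all(tr$depth[!deleted] > 0.5 * med))
  expect_true(all(tr$depth[!deleted] < 1.5 * med))
  # single-window aggregation
  expect_warning(
    one <- simulate_window_depths(g, window = 2e6, base_depth = 2, seed = 2),
    "single window")
  expect_equal(nrow(one), 1)
  expect_lt(abs(one$depth - 2), 0.1)
})

test_that("count simulation is reproducible, integer, and matches planted means", {
  cm1 <- simulate_counts(n_genes = 600, planted = 10, seed = 3)
  cm2 <- simulate_counts(n_genes = 600, planted = 10, seed = 3)
  expect_identical(cm1$counts, cm2$counts)
  expect_true(all(cm1$counts >= 0))
  expect_true(all(cm1$counts == round(cm1$counts)))

  # planted genes: empirical mean ratio positive/negative near 2^lfc
  cm <- simulate_counts(n_genes = 600, planted = 23, lfc = 2,
                        dispersion = 0.05, seed = 9)
  pos <- cm$samples$group %in% drive_positive_groups()
  planted <- cm$counts[cm$truth$planted, ]
  ratio <- rowMeans(planted[, pos]) / rowMeans(planted[, !pos])
  expect_true(median(ratio) > 3 && median(ratio) < 5.3)

  # null model: no planted effect
  cm0 <- simulate_counts(n_genes = 500, planted = character(0), lfc = 0,
                         seed = 4)
  m_pos <- mean(cm0$counts[, pos])
  m_neg <- mean(cm0$counts[, !pos])
  expect_lt(abs(log2(m_pos / m_neg)), 0.1)

  expect_error(simulate_counts(design = default_design(replicates = 3)[c(1, 4, 7), ]),
               "replicates")
})

test_that("pollen simulation conserves totals and respects class probabilities", {
  for (s in 1:10) {
    row <- simulate_pollen(112, p_loss = 0.1, p_drive = 0.9, seed = s)
    expect_equal(row$total,
                 row$none + row$vn_only + row$sn_only + row$all_nuclei)
  }
  none_drive <- simulate_pollen(500, p_drive = 0, p_vn = 0.1, seed = 1)
  expect_equal(none_drive$sn_only, 0)
  # realized drive frequency within the binomial 99% interval around 0.9
  row <- simulate_pollen(112, p_loss = 0.1, p_drive = 0.9, seed = 42)
  denom <- row$vn_only + row$sn_only + row$all_nuclei
  f <- row$sn_only / denom
  half <- qnorm(0.995) * sqrt(0.9 * 0.1 / denom)
  expect_lt(abs(f - 0.9), half + 0.02)
  expect_error(simulate_pollen(10, p_drive = 0.8, p_vn = 0.3), "<= 1")
})

test_that("simulated reads have Poisson-consistent counts and map back exactly", {
  spec <- genome_spec(host_length = 4e5, b_length = 6e5, n_genes = 0,
                      n_drive_genes = 0,
                      repeat_families = default_repeat_families()[0, ])
  g <- build_genome(spec, seed = 2)
  reads <- simulate_reads(g, depth = 1, read_len = 150, seed = 6)
  expected <- 1e6 / 150
  expect_lt(abs(length(reads) - expected), 3 * sqrt(expected))

  expect_length(simulate_reads(g, depth = 0, seed = 1), 0)

  genome_str <- paste(as.character(g$seqs), collapse = "N")
  genome_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(genome_str)))
  for (r in as.character(head(reads, 25))) {
    expect_true(grepl(r, genome_str, fixed = TRUE) ||
                  grepl(r, genome_rc, fixed = TRUE))
  }
  expect_error(simulate_reads(g, read_len = 5e5), "shortest")
})

test_that("tiling drops the final partial tile and concatenates to a prefix", {
  s <- random_seq(450)
  expect_length(tile_sequence(s, 150), 3)
  expect_length(tile_sequence(substr(s, 1, 449), 150), 2)
  tiles <- tile_sequence(s, 150)
  expect_identical(paste(as.character(tiles), collapse = ""), s)
  s2 <- random_seq(449)
  expect_identical(paste(as.character(tile_sequence(s2, 150)), collapse = ""),
                   substr(s2, 1, 300))
})

test_that("genome export writes FASTA, BED and JSON truth", {
  g <- build_genome(genome_spec(host_length = 2e4, b_length = 5e4,
                                n_genes = 3, n_drive_genes = 1,
                                repeat_families = default_repeat_families()),
                    seed = 1)
  dir <- withr::local_tempdir()
  paths <- write_genome(g, dir)
  expect_true(all(file.exists(paths)))
  fa <- Biostrings::readDNAStringSet(paths["fasta"])
  expect_identical(as.character(fa), as.character(g$seqs))
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(unlist(truth$dcr_interval), g$truth$dcr_interval)
})
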