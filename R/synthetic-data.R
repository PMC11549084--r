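#' Synthetic genomes with a supernumerary B chromosome
#'
#' The generator emulates the study system used throughout the package: a
#' host genome plus one B chromosome carrying satellite-repeat arrays in a
#' fixed zonal layout (pericentromeric Bilby and CL11; on the distal long arm
#' D1100, then Sc26c38, then E3900, with Sc9c130 most distal), genes, a
#' designated drive control region (DCR) containing planted drive genes, and
#' terminally or internally deleted karyotype variants. Every draw comes from
#' a single seeded generator so identical spec + seed gives byte-identical
#' output.
#'
#' @name synthetic-data
NULL

#' Specification for a synthetic genome
#'
#' @param host_length,b_length Chromosome lengths in bp.
#' @param repeat_families Data frame with columns `family`, `fraction`
#'   (target fraction of the B chromosome occupied by the family),
#'   `zone_start`, `zone_end` (relative positions in `[0, 1]` on the B), and
#'   `monomer_length` (bp). May have zero rows.
#' @param n_genes Number of background genes placed outside repeat arrays.
#' @param n_drive_genes Number of planted drive genes inside the DCR.
#' @param gene_length Gene length in bp.
#' @param dcr_interval Relative interval on the B designated as the drive
#'   control region.
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(host_length = 5e5,
                        b_length = 1e6,
                        repeat_families = default_repeat_families(),
                        n_genes = 30,
                        n_drive_genes = 5,
                        gene_length = 1000,
                        dcr_interval = c(0.76, 0.96)) {
  if (host_length < 1 || b_length < 1) stopf("chromosome lengths must be >= 1")
  if (nrow(repeat_families) > 0) {
    need <- c("family", "fraction", "zone_start", "zone_end", "monomer_length")
    missing <- setdiff(need, names(repeat_families))
    if (length(missing) > 0L) {
      stopf("repeat_families lacks columns: %s", paste(missing, collapse = ", "))
    }
    # reject over-subscribed zones before any sequence work
    zones <- split(repeat_families,
                   paste0(repeat_families$zone_start, "-", repeat_families$zone_end))
    for (z in zones) {
      zone_len <- (z$zone_end[1] - z$zone_start[1]) * b_length
      if (sum(z$fraction) * b_length > zone_len) {
        stopf("repeat fractions over-fill zone [%g, %g]: %.0f bp requested in a %.0f bp zone",
              z$zone_start[1], z$zone_end[1],
              sum(z$fraction) * b_length, zone_len)
      }
    }
  }
  structure(list(host_length = host_length, b_length = b_length,
                 repeat_families = repeat_families, n_genes = n_genes,
                 n_drive_genes = n_drive_genes, gene_length = gene_length,
                 dcr_interval = dcr_interval),
            class = "genome_spec")
}

#' Default repeat-family layout of the synthetic B chromosome
#'
#' Zone order mirrors the cytogenetic model of the rye B: Bilby and CL11
#' pericentromeric, then on the distal long arm D1100, Sc26c38 and E3900
#' adjacent in linear order, and Sc9c130 most distal.
#'
#' @return Data frame usable as `repeat_families` in [genome_spec()].
#' @export
default_repeat_families <- function() {
  data.frame(
    family = c("Bilby", "CL11", "D1100", "Sc26c38", "E3900", "Sc9c130"),
    fraction = c(0.03, 0.03, 0.05, 0.04, 0.04, 0.02),
    zone_start = c(0.40, 0.48, 0.76, 0.84, 0.90, 0.96),
    zone_end = c(0.48, 0.56, 0.84, 0.90, 0.96, 1.00),
    monomer_length = c(180, 120, 260, 170, 390, 150),
    stringsAsFactors = FALSE
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a synthetic genome from a specification
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed; the build is deterministic given `spec` and
#'   `seed`.
#' @return A list of class `genome_model` with elements `chromosomes`
#'   (data frame `name`, `length`, `role`), `features` (data frame `kind`,
#'   `family_or_id`, `chrom`, `start`, `end`, `strand`; 0-based half-open
#'   coordinates), `seqs` (a [Biostrings::DNAStringSet]), `truth` (planted
#'   ground truth: `dcr_interval` in bp, `planted_drive_genes`, `seed`), and
#'   `variant` (`NULL` for a reference genome).
#' @export
build_genome <- function(spec = genome_spec(), seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(derive_seed(seed, "build_genome"), {
    chroms <- data.frame(
      name = c("chrA", "chrB"),
      length = c(spec$host_length, spec$b_length),
      role = c("host", "B"),
      stringsAsFactors = FALSE
    )
    seqs <- Biostrings::DNAStringSet(c(
      chrA = random_dna(spec$host_length),
      chrB = random_dna(spec$b_length)
    ))

    features <- data.frame(kind = character(0), family_or_id = character(0),
                           chrom = character(0), start = numeric(0),
                           end = numeric(0), strand = character(0),
                           stringsAsFactors = FALSE)
    occupied <- IRanges::IRanges()  # on chrB, 1-based

    fams <- spec$repeat_families
    if (!is.null(fams) && nrow(fams) > 0) {
      for (i in seq_len(nrow(fams))) {
        fam <- fams[i, ]
        monomer <- random_dna(fam$monomer_length)
        target_bp <- round(fam$fraction * spec$b_length)
        n_units <- max(1L, floor(target_bp / fam$monomer_length))
        # split the family's units over a few tandem arrays inside its zone
        n_arrays <- max(1L, min(4L, n_units %/% 8L))
        cuts <- sort(sample(seq_len(n_units - 1L),
                            min(n_arrays - 1L, n_units - 1L)))
        unit_counts <- diff(c(0L, cuts, n_units))
        widths <- unit_counts * fam$monomer_length
        zone <- round(c(fam$zone_start, fam$zone_end) * spec$b_length)
        free <- (zone[2] - zone[1]) - sum(widths)
        if (free < 0) {
          stopf("repeat fractions over-fill zone [%g, %g] for family %s",
                fam$zone_start, fam$zone_end, fam$family)
        }
        gaps <- if (length(widths) + 1L > 1L) {
          g <- runif(length(widths) + 1L); round(free * g / sum(g))
        } else free
        starts0 <- zone[1] + cumsum(c(0, widths)) [seq_along(widths)] +
          cumsum(gaps)[seq_along(widths)]
        ends0 <- starts0 + widths
        ends0 <- pmin(ends0, spec$b_length)
        keep <- ends0 > starts0
        starts0 <- starts0[keep]; ends0 <- ends0[keep]
        unit_counts <- unit_counts[keep]
        array_seq <- vapply(unit_counts, function(u) {
          substr(strrep(monomer, ceiling(u)), 1L, u * fam$monomer_length)
        }, character(1))
        seqs[["chrB"]] <- Biostrings::replaceAt(
          seqs[["chrB"]],
          IRanges::IRanges(start = starts0 + 1L, end = ends0),
          as(array_seq, "DNAStringSet")
        )
        occupied <- c(occupied, IRanges::IRanges(starts0 + 1L, ends0))
        features <- rbind(features, data.frame(
          kind = "repeat-array", family_or_id = fam$family, chrom = "chrB",
          start = starts0, end = ends0, strand = "+",
          stringsAsFactors = FALSE
        ))
      }
    }

    dcr_bp <- round(spec$dcr_interval * spec$b_length)
    place_gene <- function(lo, hi) {
      for (try in 1:2000) {
        s0 <- floor(runif(1, lo, hi - spec$gene_length))
        cand <- IRanges::IRanges(s0 + 1L, s0 + spec$gene_length)
        if (length(occupied) == 0L ||
            sum(IRanges::countOverlaps(cand, occupied)) == 0L) {
          occupied <<- c(occupied, cand)
          return(s0)
        }
      }
      stopf("could not place a gene in [%d, %d) without overlap", lo, hi)
    }
    gene_rows <- list()
    if (spec$n_drive_genes > 0) {
      for (g in seq_len(spec$n_drive_genes)) {
        s0 <- place_gene(dcr_bp[1], dcr_bp[2])
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          kind = "gene", family_or_id = sprintf("driveg%03d", g),
          chrom = "chrB", start = s0, end = s0 + spec$gene_length,
          strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      }
    }
    if (spec$n_genes > 0) {
      for (g in seq_len(spec$n_genes)) {
        s0 <- place_gene(0, spec$b_length)
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          kind = "gene", family_or_id = sprintf("gene%04d", g),
          chrom = "chrB", start = s0, end = s0 + spec$gene_length,
          strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      }
    }
    features <- rbind(features, do.call(rbind, gene_rows))
    features <- features[order(features$chrom, features$start), ]
    rownames(features) <- NULL

    structure(list(
      chromosomes = chroms,
      features = features,
      seqs = seqs,
      truth = list(
        dcr_interval = dcr_bp,
        planted_drive_genes = grep("^driveg",
                                   features$family_or_id, value = TRUE),
        seed = seed
      ),
      variant = NULL
    ), class = "genome_model")
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %d feature(s)\n",
              nrow(x$chromosomes), nrow(x$features)))
  print(x$chromosomes)
  if (!is.null(x$variant)) {
    cat(sprintf("variant '%s': %d deletion(s), drive_positive = %s\n",
                x$variant$name, nrow(x$variant$deleted),
                x$variant$drive_positive))
  }
  invisible(x)
}

# Map reference coordinates through a set of deletions (0-based half-open).
# Positions inside a deletion collapse to the deletion start.
shift_coord <- function(x, dels) {
  vapply(x, function(p) {
    removed <- 0
    for (i in seq_len(nrow(dels))) {
      d <- dels[i, ]
      if (p >= d[2]) removed <- removed + (d[2] - d[1])
      else if (p > d[1]) removed <- removed + (p - d[1])
    }
    p - removed
  }, numeric(1))
}

#' Derive a deletion variant of a genome
#'
#' Removes one or more intervals from the B chromosome, shifting retained
#' features leftwards. The variant records the reference-coordinate
#' deletions so that coverage simulation can place zero-depth windows at the
#' right reference positions, and is flagged drive-positive unless a
#' deletion intersects the planted DCR interval.
#'
#' @param genome A `genome_model`.
#' @param variant List with `name` (text) and `deleted`: `NULL`, a length-2
#'   numeric `c(start, end)` (bp, 0-based half-open on the B chromosome), or
#'   a 2-column matrix of such intervals.
#' @return A `genome_model` whose B chromosome lacks exactly the deleted
#'   bases; `variant$drive_positive` records the drive status implied by the
#'   planted DCR.
#' @export
derive_variant <- function(genome, variant) {
  stopifnot(inherits(genome, "genome_model"))
  b_len <- genome$chromosomes$length[genome$chromosomes$role == "B"]
  dels <- variant$deleted
  if (is.null(dels) || length(dels) == 0L) {
    out <- genome
    out$variant <- list(name = variant$name %||% "variant",
                        deleted = matrix(numeric(0), ncol = 2),
                        drive_positive = TRUE,
                        reference_length = b_len)
    return(out)
  }
  if (is.null(dim(dels))) dels <- matrix(dels, ncol = 2, byrow = TRUE)
  if (any(dels[, 1] < 0) || any(dels[, 2] > b_len) ||
      any(dels[, 1] >= dels[, 2])) {
    stopf("deletion interval outside chromosome chrB [0, %d)", b_len)
  }
  dels <- dels[order(dels[, 1]), , drop = FALSE]
  if (any(dels[-1, 1] < dels[-nrow(dels), 2])) {
    stopf("deletion intervals must be disjoint")
  }

  out <- genome
  out$seqs[["chrB"]] <- Biostrings::replaceAt(
    genome$seqs[["chrB"]],
    IRanges::IRanges(start = dels[, 1] + 1L, end = dels[, 2]),
    as(rep("", nrow(dels)), "DNAStringSet")
  )
  removed <- sum(dels[, 2] - dels[, 1])
  out$chromosomes$length[out$chromosomes$role == "B"] <- b_len - removed

  feats <- genome$features
  onb <- feats$chrom == "chrB"
  ns <- shift_coord(feats$start, dels)
  ne <- shift_coord(feats$end, dels)
  feats$start[onb] <- ns[onb]
  feats$end[onb] <- ne[onb]
  feats <- feats[feats$end > feats$start, ]
  rownames(feats) <- NULL
  out$features <- feats

  dcr <- genome$truth$dcr_interval
  dcr_hit <- any(pmin(dels[, 2], dcr[2]) > pmax(dels[, 1], dcr[1]))
  out$variant <- list(name = variant$name %||% "variant",
                      deleted = dels,
                      drive_positive = !dcr_hit,
                      reference_length = b_len)
  out
}

#' Collapse repeat arrays of one family in an assembly
#'
#' Emulates assembly breakdown in long satellite arrays: each array of the
#' family keeps only its first `keep_fraction` of bases, the rest are removed
#' from the sequence. Used to plant a known assembly-completeness deficit.
#'
#' @param genome A `genome_model`.
#' @param family Repeat family name.
#' @param keep_fraction Fraction of each array retained, in `[0, 1]`.
#' @return A `genome_model` with the family's arrays shortened.
#' @export
collapse_arrays <- function(genome, family, keep_fraction) {
  stopifnot(inherits(genome, "genome_model"))
  if (keep_fraction < 0 || keep_fraction > 1) {
    stopf("keep_fraction must lie in [0, 1]")
  }
  f <- genome$features
  sel <- f$kind == "repeat-array" & f$family_or_id == family
  if (!any(sel)) stopf("no arrays of family '%s' in the genome", family)
  width <- f$end[sel] - f$start[sel]
  cut <- round(width * keep_fraction)
  dels <- cbind(f$start[sel] + cut, f$end[sel])
  dels <- dels[dels[, 2] > dels[, 1], , drop = FALSE]
  if (nrow(dels) == 0L) return(genome)
  derive_variant(genome, list(name = paste0("collapse_", family),
                              deleted = dels))
}

#' Simulate per-contig mean sequencing depths
#'
#' Per-contig mean depth is drawn from a gamma law with mean
#' `base_depth * multiplicity` and variance `dispersion * mean^2` — the
#' mixing distribution of a negative binomial, appropriate for the
#' *average* depth over a long contig where counting noise is negligible.
#' `dispersion = 0` returns the exact means.
#'
#' @param contigs Data frame with columns `contig` and `length`, or a
#'   character vector of names (lengths then default to 100 kb).
#' @param multiplicity Copy number per contig: a single number or a vector
#'   recycled along contigs. Host contigs have multiplicity 1; a B
#'   chromosome present at ~3 copies per host genome equivalent has
#'   multiplicity ~3.
#' @param base_depth Depth of a single-copy contig, in x.
#' @param dispersion Squared coefficient of variation of contig depth.
#' @param seed Integer seed.
#' @return Data frame `contig`, `length`, `mean_depth`.
#' @export
simulate_contig_depths <- function(contigs, multiplicity = 1,
                                   base_depth = 14, dispersion = 0.05,
                                   seed = 1L) {
  if (is.character(contigs)) {
    contigs <- data.frame(contig = contigs, length = 1e5,
                          stringsAsFactors = FALSE)
  }
  if (base_depth <= 0) stopf("base_depth must be > 0")
  if (any(multiplicity < 1)) stopf("multiplicity must be >= 1")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  n <- nrow(contigs)
  mu <- base_depth * rep_len(multiplicity, n)
  depth <- if (dispersion == 0) {
    mu
  } else {
    with_seed(derive_seed(seed, "contig_depths"), {
      stats::rgamma(n, shape = 1 / dispersion, scale = mu * dispersion)
    })
  }
  data.frame(contig = contigs$contig, length = contigs$length,
             mean_depth = depth, stringsAsFactors = FALSE)
}

#' Simulate a windowed depth-of-coverage track
#'
#' Reads are modeled as Poisson base coverage: each window's depth is a
#' Poisson draw with mean `base_depth * retained window length`, divided by
#' the window length. Windows overlapping a recorded deletion of a variant
#' genome receive coverage only for their retained fraction (zero for fully
#' deleted windows). Coordinates are on the *reference* B chromosome so
#' tracks of different variants are comparable.
#'
#' @param genome A `genome_model`, possibly variant-derived.
#' @param window Window size in bp.
#' @param base_depth Expected depth in covered regions.
#' @param seed Integer seed.
#' @param chrom Chromosome to simulate (default the B chromosome).
#' @return A data frame of class `coverage_track` with columns `chrom`,
#'   `start`, `end` (0-based half-open) and `depth`; attributes `line`
#'   (variant name) and `window`.
#' @export
simulate_window_depths <- function(genome, window = 1e4, base_depth = 2,
                                   seed = 1L, chrom = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  if (window < 1) stopf("window must be >= 1")
  if (is.null(chrom)) {
    chrom <- genome$chromosomes$name[genome$chromosomes$role == "B"][1]
  }
  ref_len <- if (!is.null(genome$variant)) {
    genome$variant$reference_length
  } else {
    genome$chromosomes$length[genome$chromosomes$name == chrom]
  }
  if (window > ref_len) {
    warnf("window (%g) exceeds chromosome length (%g); using a single window",
          window, ref_len)
    window <- ref_len
  }
  starts <- seq(0, ref_len - 1, by = window)
  ends <- pmin(starts + window, ref_len)
  retained <- ends - starts
  if (!is.null(genome$variant) && nrow(genome$variant$deleted) > 0) {
    dels <- genome$variant$deleted
    for (i in seq_len(nrow(dels))) {
      ov <- pmin(ends, dels[i, 2]) - pmax(starts, dels[i, 1])
      retained <- retained - pmax(ov, 0)
    }
  }
  depth <- with_seed(derive_seed(seed, paste0("window_depths_",
                                              genome$variant$name %||% "ref")), {
    rpois(length(starts), base_depth * retained) / (ends - starts)
  })
  out <- data.frame(chrom = chrom, start = starts, end = ends, depth = depth,
                    stringsAsFactors = FALSE)
  attr(out, "line") <- genome$variant$name %||% "reference"
  attr(out, "window") <- window
  class(out) <- c("coverage_track", "data.frame")
  out
}

#' Default RNA-seq sample design
#'
#' Nine genotype groups — wheat with 0B, 2Bs, 4Bs, 1Bk-2, 1Bs-8 or 1Bk-1,
#' and rye with 0B, 2B or 1defB — covering the eleven drive-positive versus
#' drive-negative comparisons of the subtractive funnel, with a fixed number
#' of replicates each.
#'
#' @param replicates Replicates per group (>= 2).
#' @return Data frame with columns `sample` and `group`.
#' @export
default_design <- function(replicates = 3) {
  if (replicates < 2) stopf("at least 2 replicates per group are required")
  groups <- c("wheat_0B", "wheat_2Bs", "wheat_4Bs", "wheat_1Bk2",
              "wheat_1Bs8", "wheat_1Bk1", "rye_0B", "rye_2B", "rye_1defB")
  data.frame(
    sample = paste0(rep(groups, each = replicates), "_r",
                    rep(seq_len(replicates), length(groups))),
    group = rep(groups, each = replicates),
    stringsAsFactors = FALSE
  )
}

#' Groups carrying a drive-positive B chromosome in the default design
#' @return Character vector of group names.
#' @export
drive_positive_groups <- function() {
  c("wheat_2Bs", "wheat_4Bs", "wheat_1Bk2", "rye_2B")
}

#' Simulate an RNA-seq count matrix with planted drive genes
#'
#' Baseline per-gene means are lognormal; counts are negative binomial with
#' a common dispersion and per-sample library-size factors. Planted drive
#' genes have their mean multiplied by `2^lfc` in drive-positive groups
#' only; all other genes are exchangeable across groups. Planted baselines
#' are drawn from the well-expressed range (lognormal around
#' `planted_base_mean`), emulating that candidate drive genes are robustly
#' transcribed in the tissue assayed — a count-based funnel can only ever
#' recover detectably expressed genes.
#'
#' @param n_genes Number of genes.
#' @param design Sample sheet as from [default_design()].
#' @param planted Character vector of planted drive gene ids (must be among
#'   the generated gene ids `gene0001...`), or an integer count (the first
#'   `planted` genes are used).
#' @param lfc Planted effect, log2 fold change.
#' @param dispersion NB dispersion (0 gives Poisson counts).
#' @param libsize_range Range of uniform per-sample library-size factors.
#' @param seed Integer seed.
#' @param positive_groups Groups in which planted genes are upregulated.
#' @param planted_base_mean Median baseline mean of planted drive genes.
#' @return A list of class `count_matrix`: integer matrix `counts`
#'   (genes x samples), data frame `samples`, and `truth` (planted ids, lfc).
#' @export
simulate_counts <- function(n_genes = 2000, design = default_design(),
                            planted = 23, lfc = 2, dispersion = 0.05,
                            libsize_range = c(0.7, 1.3), seed = 1L,
                            positive_groups = drive_positive_groups(),
                            planted_base_mean = 300) {
  reps <- table(design$group)
  if (any(reps < 2)) {
    stopf("groups with < 2 replicates: %s (dispersion not estimable)",
          paste(names(reps)[reps < 2], collapse = ", "))
  }
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  if (is.numeric(planted) && length(planted) == 1L) {
    planted <- head(gene_ids, planted)
  }
  if (!all(planted %in% gene_ids)) stopf("planted ids not among gene ids")
  with_seed(derive_seed(seed, "simulate_counts"), {
    base_mu <- rlnorm(n_genes, meanlog = log(100), sdlog = 1)
    is_planted <- gene_ids %in% planted
    base_mu[is_planted] <- rlnorm(sum(is_planted),
                                  meanlog = log(planted_base_mean),
                                  sdlog = 0.5)
    libf <- runif(nrow(design), libsize_range[1], libsize_range[2])
    mu <- outer(base_mu, libf)
    pos_cols <- design$group %in% positive_groups
    planted_rows <- gene_ids %in% planted
    mu[planted_rows, pos_cols] <- mu[planted_rows, pos_cols] * 2^lfc
    counts <- if (dispersion == 0) {
      matrix(rpois(length(mu), mu), nrow = n_genes)
    } else {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             nrow = n_genes)
    }
    dimnames(counts) <- list(gene_ids, design$sample)
    structure(list(counts = counts, samples = design,
                   truth = list(planted = planted, lfc = lfc, seed = seed)),
              class = "count_matrix")
  })
}

#' Simulate a pollen-FISH count row
#'
#' Each pollen is assigned no-signal with probability `p_loss` (meiotic or
#' post-meiotic B loss); otherwise sperm-nuclei-only with `p_drive`,
#' vegetative-only with `p_vn`, and all-nuclei with the remainder.
#'
#' @param n Number of pollen scored.
#' @param p_loss,p_drive,p_vn Probabilities; `p_drive + p_vn <= 1`.
#'   `p_vn` defaults to `0.05 * p_drive`, matching the small
#'   vegetative-only class seen in real tables.
#' @param seed Integer seed.
#' @param variant Label for the `variant` column.
#' @return One-row data frame in the pollen-table schema.
#' @export
simulate_pollen <- function(n, p_loss = 0.1, p_drive = 0.9,
                            p_vn = 0.05 * p_drive, seed = 1L,
                            variant = "synthetic") {
  probs <- c(p_loss, p_drive, p_vn)
  if (any(probs < 0) || any(c(p_loss, p_drive, p_vn) > 1)) {
    stopf("probabilities must lie in [0, 1]")
  }
  if (p_drive + p_vn > 1) stopf("p_drive + p_vn must be <= 1")
  class_p <- c(none = p_loss,
               sn_only = (1 - p_loss) * p_drive,
               vn_only = (1 - p_loss) * p_vn,
               all_nuclei = (1 - p_loss) * (1 - p_drive - p_vn))
  cnt <- with_seed(derive_seed(seed, "simulate_pollen"), {
    drop(rmultinom(1, n, class_p))
  })
  data.frame(variant = variant, total = n,
             none = cnt[["none"]], vn_only = cnt[["vn_only"]],
             sn_only = cnt[["sn_only"]], all_nuclei = cnt[["all_nuclei"]],
             stringsAsFactors = FALSE)
}

#' Simulate error-free fixed-length reads
#'
#' Uniform start positions on both strands, error-free substrings; the read
#' count is Poisson with expectation `depth * genome_length / read_len`.
#'
#' @param genome A `genome_model`.
#' @param depth Target coverage in x.
#' @param read_len Read length in bp.
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet] of reads.
#' @export
simulate_reads <- function(genome, depth = 1, read_len = 150, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  if (depth < 0) stopf("depth must be >= 0")
  lens <- genome$chromosomes$length
  if (read_len > min(lens)) {
    stopf("read_len (%d) exceeds the shortest chromosome (%d bp)",
          read_len, min(lens))
  }
  g_len <- sum(lens)
  with_seed(derive_seed(seed, "simulate_reads"), {
    n <- rpois(1, depth * g_len / read_len)
    if (n == 0) return(Biostrings::DNAStringSet())
    chrom_idx <- sample.int(nrow(genome$chromosomes), n, replace = TRUE,
                            prob = lens)
    starts <- floor(runif(n, 1, lens[chrom_idx] - read_len + 2))
    minus <- runif(n) < 0.5
    reads <- Biostrings::DNAStringSet(
      genome$seqs[chrom_idx],
      start = starts, width = read_len
    )
    reads[minus] <- Biostrings::reverseComplement(reads[minus])
    names(reads) <- sprintf("read%07d", seq_len(n))
    reads
  })
}

#' Cut a sequence into non-overlapping fixed-length tiles
#'
#' Consecutive `k`-bp tiles; a final partial tile shorter than `k` is
#' discarded so tiles and same-length reads stay unit-comparable in the
#' completeness ratio.
#'
#' @param seq A character string, [Biostrings::DNAString] or a
#'   [Biostrings::DNAStringSet] (tiled per element).
#' @param k Tile length in bp.
#' @return A [Biostrings::DNAStringSet] of tiles.
#' @export
tile_sequence <- function(seq, k = 150) {
  if (k < 1) stopf("k must be >= 1")
  if (is(seq, "DNAStringSet")) {
    tiles <- lapply(seq_along(seq), function(i) tile_sequence(seq[[i]], k))
    return(do.call(c, tiles))
  }
  s <- Biostrings::DNAString(as.character(seq))
  n <- length(s) %/% k
  if (n == 0) return(Biostrings::DNAStringSet())
  starts <- (seq_len(n) - 1L) * k + 1L
  Biostrings::DNAStringSet(
    Biostrings::extractAt(s, IRanges::IRanges(starts, width = k))
  )
}

#' Fragment a chromosome into contigs with known true order
#'
#' Splits a chromosome at random positions into `n_pieces` contigs, carries
#' the repeat-array annotations over to contig-local coordinates, and
#' records the true contig order — input for ordering-recovery experiments.
#'
#' @param genome A `genome_model`.
#' @param n_pieces Number of contigs.
#' @param chrom Chromosome to fragment (default the B).
#' @param seed Integer seed.
#' @return List with `contig_lengths` (named, in true order),
#'   `annotations` (data frame `contig`, `family`, `start`, `end`),
#'   `true_order` (character), `breaks` (bp).
#' @export
fragment_chromosome <- function(genome, n_pieces, chrom = "chrB", seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  len <- genome$chromosomes$length[genome$chromosomes$name == chrom]
  if (n_pieces < 1 || n_pieces > len) stopf("invalid n_pieces")
  breaks <- with_seed(derive_seed(seed, "fragment"), {
    sort(sample(seq_len(len - 1), n_pieces - 1))
  })
  bounds <- c(0, breaks, len)
  ids <- sprintf("ctg%03d", seq_len(n_pieces))
  lens <- diff(bounds)
  names(lens) <- ids
  feats <- genome$features
  feats <- feats[feats$chrom == chrom & feats$kind == "repeat-array", ]
  ann <- list()
  for (i in seq_len(n_pieces)) {
    lo <- bounds[i]; hi <- bounds[i + 1]
    ov <- pmin(feats$end, hi) - pmax(feats$start, lo)
    sel <- which(ov > 0)
    if (length(sel) > 0) {
      ann[[length(ann) + 1L]] <- data.frame(
        contig = ids[i],
        family = feats$family_or_id[sel],
        start = pmax(feats$start[sel], lo) - lo,
        end = pmin(feats$end[sel], hi) - lo,
        stringsAsFactors = FALSE)
    }
  }
  annotations <- if (length(ann) > 0) {
    do.call(rbind, ann)
  } else {
    data.frame(contig = character(0), family = character(0),
               start = numeric(0), end = numeric(0))
  }
  list(contig_lengths = lens, annotations = annotations,
       true_order = ids, breaks = breaks)
}

#' Write a genome as FASTA plus BED features and JSON truth
#'
#' @param genome A `genome_model`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_genome <- function(genome, dir, prefix = "genome") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  bed <- file.path(dir, paste0(prefix, "_features.bed"))
  truth <- file.path(dir, paste0(prefix, "_truth.json"))
  Biostrings::writeXStringSet(genome$seqs, fa)
  feats <- genome$features
  write.table(
    data.frame(chrom = feats$chrom, start = feats$start, end = feats$end,
               name = paste(feats$kind, feats$family_or_id, sep = ":"),
               score = 0, strand = feats$strand),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(genome$truth, truth, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, bed = bed, truth = truth))
}
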