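#' End-to-end analysis pipeline
#'
#' [run_pipeline()] chains the package's stages on a synthetic study system
#' with known ground truth: genome + variant simulation, coverage-based
#' contig classification, landmark ordering, DCR deletion mapping,
#' repeat-assembly completeness, the subtractive DE funnel, and pollen-FISH
#' drive statistics. Every output file is written under `outdir` and listed
#' in a JSON manifest with content hashes, the seed and a config hash, so a
#' rerun with the same config is verifiably identical.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' Reference analysis defaults: 1 Mb windows scaled to the toy genome,
#' presence threshold alpha = 0.1, log2 fold-change cut 1, adjusted-p cut
#' 0.01, clustering identity 0.8, ORF rule > 100 aa.
#'
#' @param seed Integer master seed; all stage seeds derive from it.
#' @return Nested list of stage parameters.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = seed,
    genome = list(host_length = 3e5, b_length = 6e5),
    variants = list(
      # deletions are relative to the B length (empty = standard B); drive
      # status follows from overlap with the planted DCR (0.76-0.96)
      Bs = numeric(0),
      Bk2 = c(0.965, 1),
      Bk3 = c(0.86, 1)
    ),
    classify = list(n_host = 150, n_b = 50, base_depth = 14,
                    multiplicity = 44 / 14, dispersion = 0.05),
    order = list(n_pieces = 6),
    delimit = list(window = 1e4, base_depth = 2, alpha = 0.1, merge_gap = 2),
    completeness = list(family = "E3900", keep_fraction = 0.67, k = 31,
                        min_kmer_frac = 0.5),
    funnel = list(n_genes = 400, planted = 10, lfc = 2, dispersion = 0.05,
                  replicates = 3),
    pollen = list(n = 112, p_loss = 0.1, p_drive = 0.9)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  base <- default_pipeline_config()
  utils::modifyList(base, config)
}

#' Run the full pipeline
#'
#' @param config A config list (see [default_pipeline_config()]) or path to
#'   a YAML file with overrides. Any file path referenced in the config
#'   must exist at launch.
#' @param outdir Output directory.
#' @return List of class `pipeline_result` with per-stage results and the
#'   manifest. Side effect: output files plus `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir) {
  cfg <- read_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  paths <- character(0)
  note <- function(p) paths <<- c(paths, p)

  # --- simulate ------------------------------------------------------------
  spec <- genome_spec(host_length = cfg$genome$host_length,
                      b_length = cfg$genome$b_length)
  genome <- build_genome(spec, seed = seed)
  note(write_genome(genome, outdir, "reference"))
  b_len <- spec$b_length
  variants <- lapply(names(cfg$variants), function(v) {
    rel <- unlist(cfg$variants[[v]])
    del <- if (length(rel) == 0) NULL else round(rel * b_len)
    derive_variant(genome, list(name = v, deleted = del))
  })
  names(variants) <- names(cfg$variants)

  # --- classify ------------------------------------------------------------
  cl <- cfg$classify
  contigs <- data.frame(
    contig = sprintf("ctg%04d", seq_len(cl$n_host + cl$n_b)),
    length = rep(1e5, cl$n_host + cl$n_b))
  depths <- simulate_contig_depths(
    contigs, multiplicity = rep(c(1, cl$multiplicity), c(cl$n_host, cl$n_b)),
    base_depth = cl$base_depth, dispersion = cl$dispersion,
    seed = derive_seed(seed, "classify"))
  fit <- fit_depth_mixture(depths)
  labels <- assign_contigs(depths, fit$threshold)
  assignment <- summarize_assignment(labels, depths)
  p <- file.path(outdir, "contig_labels.tsv")
  write.table(labels, p, sep = "\t", quote = FALSE, row.names = FALSE)
  note(p)
  p <- file.path(outdir, "mixture_fit.json")
  jsonlite::write_json(unclass(fit)[c("component_means", "weights",
                                      "threshold", "method", "converged")],
                       p, auto_unbox = TRUE, digits = NA)
  note(p)

  # --- order ---------------------------------------------------------------
  frag <- fragment_chromosome(genome, cfg$order$n_pieces, seed = seed)
  profiles <- profile_contigs(frag$annotations, frag$contig_lengths)
  model <- default_landmark_model()
  arrangement <- best_order(profiles, model, mode = "greedy")
  p <- file.path(outdir, "arrangement.tsv")
  write_agp(arrangement, profiles, p)
  note(p)

  # --- delimit DCR ---------------------------------------------------------
  dl <- cfg$delimit
  tracks <- lapply(variants, simulate_window_depths, window = dl$window,
                   base_depth = dl$base_depth,
                   seed = derive_seed(seed, "delimit"))
  pm <- presence_matrix(tracks, alpha = dl$alpha)
  pos_lines <- names(variants)[vapply(variants,
                                      function(v) v$variant$drive_positive,
                                      logical(1))]
  neg_lines <- setdiff(names(variants), pos_lines)
  dcr <- delimit_region(pm, pos_lines, neg_lines, merge_gap = dl$merge_gap)
  note(write_dcr_report(dcr, pm, outdir))

  # --- repeat completeness -------------------------------------------------
  cp <- cfg$completeness
  collapsed <- collapse_arrays(genome, cp$family, cp$keep_fraction)
  reads <- simulate_reads(genome, depth = 1,
                          seed = derive_seed(seed, "completeness"))
  fam_feats <- genome$features[genome$features$kind == "repeat-array", ]
  lib <- Biostrings::DNAStringSet(vapply(
    unique(fam_feats$family_or_id), function(f) {
      row <- fam_feats[fam_feats$family_or_id == f, ][1, ]
      as.character(Biostrings::subseq(genome$seqs[[row$chrom]],
                                      row$start + 1, row$end))
    }, character(1)))
  comp <- completeness(collapsed$seqs[["chrB"]], reads,
                       host = genome$seqs[["chrA"]], library = lib,
                       k = cp$k, min_kmer_frac = cp$min_kmer_frac,
                       genome_size = sum(genome$chromosomes$length))
  p <- file.path(outdir, "completeness.tsv")
  write_completeness(comp, p)
  note(p)

  # --- DE funnel -----------------------------------------------------------
  fu <- cfg$funnel
  counts <- simulate_counts(n_genes = fu$n_genes,
                            design = default_design(fu$replicates),
                            planted = fu$planted, lfc = fu$lfc,
                            dispersion = fu$dispersion,
                            seed = derive_seed(seed, "funnel"))
  funnel <- run_funnel(counts, default_funnel_config())
  p <- file.path(outdir, "funnel.json")
  jsonlite::write_json(list(stage_counts = funnel$stage_counts,
                            final = funnel$final),
                       p, auto_unbox = TRUE, digits = NA)
  note(p)

  # --- drive stats ---------------------------------------------------------
  po <- cfg$pollen
  pollen <- do.call(rbind, lapply(names(variants), function(v) {
    drive_pos <- variants[[v]]$variant$drive_positive
    simulate_pollen(po$n, p_loss = po$p_loss,
                    p_drive = if (drive_pos) po$p_drive else 0,
                    seed = derive_seed(seed, paste0("pollen_", v)),
                    variant = v)
  }))
  est <- drive_table(pollen)
  p <- file.path(outdir, "drive_estimates.tsv")
  write.table(est, p, sep = "\t", quote = FALSE, row.names = FALSE)
  note(p)

  # --- manifest ------------------------------------------------------------
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  cfg_file <- file.path(outdir, "config.json")
  writeLines(cfg_json, cfg_file)
  note(cfg_file)
  files <- sort(unique(unlist(paths, use.names = FALSE)))
  manifest <- list(
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(genome = genome, variants = variants, fit = fit,
                 assignment = assignment, arrangement = arrangement,
                 dcr = dcr, completeness = comp, funnel = funnel,
                 drive = est, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  mixture threshold: %.1fx (converged: %s)\n",
              x$fit$threshold, x$fit$converged))
  cat(sprintf("  ordering score: %.2f\n", x$arrangement$score))
  if (nrow(x$dcr) > 0) {
    cand <- x$dcr[x$dcr$candidate, ]
    cat(sprintf("  candidate DCR: %s:%d-%d (%d windows)\n", cand$chrom,
                cand$start_1based, cand$end, cand$n_windows))
  }
  cat("  funnel:", paste(x$funnel$stage_counts, collapse = " -> "), "\n")
  invisible(x)
}
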