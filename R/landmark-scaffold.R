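#' Landmark-guided contig ordering
#'
#' B-assigned contigs are ordered and oriented into a pseudomolecule by
#' matching the positions of satellite-repeat landmarks on the contigs
#' against a model of the chromosome-wide repeat layout. The objective is
#' rank concordance: an arrangement scores highly when the
#' abundance-weighted centroid of each landmark family along the
#' concatenated arrangement ranks in the same order as the family's expected
#' relative chromosomal position.
#'
#' @name landmark-scaffold
NULL

#' Build repeat profiles of contigs from feature annotations
#'
#' @param annotations Data frame with columns `contig`, `family`, `start`,
#'   `end` (0-based half-open bp on the contig).
#' @param contig_lengths Named numeric vector of contig lengths.
#' @return A list of class `repeat_profiles`: numeric matrices `abundance`
#'   (bp) and `centroid` (length-weighted mean feature midpoint divided by
#'   contig length, `NA` where abundance is 0), both contigs x families, and
#'   `lengths`.
#' @export
profile_contigs <- function(annotations, contig_lengths) {
  contigs <- names(contig_lengths)
  if (is.null(contigs)) stopf("contig_lengths must be a named vector")
  if (nrow(annotations) > 0) {
    bad <- !(annotations$contig %in% contigs)
    if (any(bad)) {
      stopf("annotation on unknown contig: %s",
            paste(unique(annotations$contig[bad]), collapse = ", "))
    }
    over <- annotations$end > contig_lengths[annotations$contig] |
      annotations$start < 0 | annotations$start >= annotations$end
    if (any(over)) {
      i <- which(over)[1]
      stopf("feature %s:[%g, %g) lies outside contig %s (length %g)",
            annotations$family[i], annotations$start[i], annotations$end[i],
            annotations$contig[i], contig_lengths[annotations$contig[i]])
    }
  }
  families <- sort(unique(annotations$family))
  A <- matrix(0, length(contigs), length(families),
              dimnames = list(contigs, families))
  Cm <- matrix(NA_real_, length(contigs), length(families),
               dimnames = list(contigs, families))
  if (nrow(annotations) > 0) {
    w <- annotations$end - annotations$start
    mid <- (annotations$start + annotations$end) / 2
    for (f in families) {
      sel <- annotations$family == f
      ab <- tapply(w[sel], annotations$contig[sel], sum)
      wm <- tapply(w[sel] * mid[sel], annotations$contig[sel], sum)
      A[names(ab), f] <- ab
      Cm[names(ab), f] <- (wm / ab) / contig_lengths[names(ab)]
    }
  }
  structure(list(abundance = A, centroid = Cm, lengths = contig_lengths),
            class = "repeat_profiles")
}

#' Landmark model: expected relative positions of repeat families
#'
#' @param families Character vector of family names in chromosomal order.
#' @param positions Strictly increasing relative positions in `[0, 1]`.
#' @return Data frame of class `landmark_model` with columns `family`,
#'   `position`.
#' @export
landmark_model <- function(families, positions) {
  if (length(families) != length(positions)) {
    stopf("families and positions must have equal length")
  }
  if (any(diff(positions) <= 0)) stopf("positions must be strictly increasing")
  structure(data.frame(family = families, position = positions,
                       stringsAsFactors = FALSE),
            class = c("landmark_model", "data.frame"))
}

#' Default landmark model matching the synthetic B chromosome layout
#' @return A [landmark_model()] with zone-midpoint positions of the default
#'   repeat families.
#' @export
default_landmark_model <- function() {
  fams <- default_repeat_families()
  landmark_model(fams$family, (fams$zone_start + fams$zone_end) / 2)
}

# Observed abundance-weighted centroid of each model family along a
# concatenated arrangement, as a fraction of total length. Orientation "-"
# mirrors within-contig centroids (c -> 1 - c).
arrangement_centroids <- function(arrangement, profiles, model) {
  ord <- arrangement$order
  ori <- arrangement$orientation %||% rep("+", length(ord))
  lens <- profiles$lengths[ord]
  offsets <- cumsum(c(0, lens))[seq_along(ord)]
  total <- sum(lens)
  fams <- intersect(model$family, colnames(profiles$abundance))
  cent <- rep(NA_real_, length(fams)); names(cent) <- fams
  for (f in fams) {
    a <- profiles$abundance[ord, f]
    if (sum(a) == 0) next
    cc <- profiles$centroid[ord, f]
    cc[ori == "-"] <- 1 - cc[ori == "-"]
    pos <- offsets + lens * cc
    cent[f] <- sum(a * pos, na.rm = TRUE) / sum(a) / total
  }
  cent
}

#' Score an arrangement against a landmark model
#'
#' The score is `F * rho`, where `F` is the number of model families with
#' nonzero abundance in the arrangement and `rho` is the Spearman rank
#' correlation between the families' observed centroid positions along the
#' concatenated arrangement and their model positions. A perfectly
#' concordant arrangement scores `F`, a fully reversed one `-F`.
#'
#' @param arrangement List with `order` (character, every contig exactly
#'   once) and optional `orientation` (`"+"`/`"-"`, default all `"+"`).
#' @param profiles A `repeat_profiles` object.
#' @param model A `landmark_model`.
#' @return Numeric score in `[-F, F]`.
#' @export
order_score <- function(arrangement, profiles, model) {
  contigs <- rownames(profiles$abundance)
  if (!setequal(arrangement$order, contigs) ||
      length(arrangement$order) != length(contigs)) {
    stopf("arrangement must cover every contig exactly once")
  }
  cent <- arrangement_centroids(arrangement, profiles, model)
  ok <- !is.na(cent)
  f_count <- sum(ok)
  if (f_count < 2) return(0)
  mpos <- model$position[match(names(cent)[ok], model$family)]
  rho <- stats::cor(cent[ok], mpos, method = "spearman")
  if (is.na(rho)) return(0)
  f_count * rho
}

perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub], nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

# Vectorized exhaustive search: for one permutation, score all 2^n
# orientation patterns with a single matrix product, ranking family
# centroids with pairwise comparisons (average ranks under ties), which
# reproduces stats::cor(method = "spearman") exactly.
exhaustive_order <- function(profiles, model) {
  contigs <- rownames(profiles$abundance)
  n <- length(contigs)
  fams <- intersect(model$family, colnames(profiles$abundance))
  fams <- fams[colSums(profiles$abundance[, fams, drop = FALSE]) > 0]
  f_count <- length(fams)
  if (f_count < 2) {
    return(list(order = contigs, orientation = rep("+", n), score = 0))
  }
  mpos <- model$position[match(fams, model$family)]
  r_mod <- rank(mpos)

  O <- as.matrix(expand.grid(rep(list(0:1), n)))  # 2^n orientation rows
  A <- profiles$abundance[, fams, drop = FALSE]
  Cm <- profiles$centroid[, fams, drop = FALSE]
  Cm[is.na(Cm)] <- 0
  lens <- profiles$lengths[contigs]
  total <- sum(lens)
  Af <- colSums(A)

  perms <- perms_of(n)
  best <- list(score = -Inf)
  rmod_c <- r_mod - mean(r_mod)
  den_mod <- sum(rmod_c^2)
  for (p in seq_len(nrow(perms))) {
    idx <- perms[p, ]
    off <- cumsum(c(0, lens[idx]))[seq_len(n)]
    # per-family centroid = base + O %*% delta (orientation flips c -> 1-c)
    base_term <- A[idx, , drop = FALSE] *
      (off + lens[idx] * Cm[idx, , drop = FALSE])
    flip_term <- A[idx, , drop = FALSE] *
      (off + lens[idx] * (1 - Cm[idx, , drop = FALSE]))
    base <- colSums(base_term)
    D <- flip_term - base_term
    cent <- (matrix(base, nrow(O), f_count, byrow = TRUE) + O %*% D) /
      matrix(Af * total, nrow(O), f_count, byrow = TRUE)
    # average ranks via pairwise comparisons, vectorized over rows
    R <- matrix(1, nrow(O), f_count)
    for (j in seq_len(f_count)) {
      for (k in seq_len(f_count)) {
        if (k == j) next
        R[, j] <- R[, j] + (cent[, k] < cent[, j]) +
          0.5 * (cent[, k] == cent[, j])
      }
    }
    Rc <- R - rowMeans(R)
    num <- Rc %*% rmod_c
    den <- sqrt(rowSums(Rc^2) * den_mod)
    rho <- ifelse(den == 0, 0, num / den)
    scores <- f_count * rho
    b <- which.max(scores)
    if (scores[b] > best$score + 1e-12) {
      best <- list(order = contigs[idx],
                   orientation = c("+", "-")[O[b, ] + 1L],
                   score = scores[b])
    }
  }
  best
}

greedy_order <- function(profiles, model, max_sweeps = 10L) {
  contigs <- rownames(profiles$abundance)
  lens <- profiles$lengths[contigs]
  # deterministic multi-start: primary insertion order is decreasing length
  # (ties by name); alternative seeds order contigs by the model position of
  # their dominant landmark family, and by name
  dom_pos <- vapply(contigs, function(ct) {
    a <- profiles$abundance[ct, ]
    if (sum(a) == 0) return(Inf)
    fam <- colnames(profiles$abundance)[which.max(a)]
    m <- match(fam, model$family)
    if (is.na(m)) Inf else model$position[m]
  }, numeric(1))
  starts <- list(contigs[order(-lens, contigs)],
                 contigs[order(dom_pos, contigs)],
                 sort(contigs))
  best_res <- NULL
  for (ins_order in unique(starts)) {
    res <- greedy_from(profiles, model, ins_order, max_sweeps)
    if (is.null(best_res) || res$score > best_res$score + 1e-12) {
      best_res <- res
    }
  }
  best_res
}

greedy_from <- function(profiles, model, ins_order, max_sweeps) {
  ord <- character(0); ori <- character(0)
  for (ct in ins_order) {
    best <- NULL; best_score <- -Inf
    for (pos in seq_len(length(ord) + 1L)) {
      for (o in c("+", "-")) {
        cand_ord <- append(ord, ct, after = pos - 1L)
        cand_ori <- append(ori, o, after = pos - 1L)
        sub <- subset_profiles(profiles, cand_ord)
        sc <- order_score(list(order = cand_ord, orientation = cand_ori),
                          sub, model)
        if (sc > best_score + 1e-12) {
          best_score <- sc
          best <- list(order = cand_ord, orientation = cand_ori)
        }
      }
    }
    ord <- best$order; ori <- best$orientation
  }
  # relocation sweeps: early insertions are scored on few landmark families
  # and can lock in a bad prefix; re-seat each contig until no move helps
  score_of <- function(o, r) {
    order_score(list(order = o, orientation = r), profiles, model)
  }
  cur <- score_of(ord, ori)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (ct in ins_order) {
      at <- match(ct, ord)
      rest_ord <- ord[-at]; rest_ori <- ori[-at]
      best_sc <- cur; best_cand <- NULL
      for (pos in seq_len(length(rest_ord) + 1L)) {
        for (o in c("+", "-")) {
          cand_ord <- append(rest_ord, ct, after = pos - 1L)
          cand_ori <- append(rest_ori, o, after = pos - 1L)
          sc <- score_of(cand_ord, cand_ori)
          if (sc > best_sc + 1e-12) {
            best_sc <- sc
            best_cand <- list(ord = cand_ord, ori = cand_ori)
          }
        }
      }
      if (!is.null(best_cand)) {
        ord <- best_cand$ord; ori <- best_cand$ori; cur <- best_sc
        improved <- TRUE
      }
    }
    # pairwise swaps and block reversals escape local optima the
    # single-contig moves cannot; reversal (with orientation flips) is the
    # natural move under a rank-concordance objective
    n <- length(ord)
    if (n >= 2) {
      for (i in 1:(n - 1)) {
        for (j in (i + 1):n) {
          cand_ord <- ord; cand_ord[c(i, j)] <- ord[c(j, i)]
          cand_ori <- ori; cand_ori[c(i, j)] <- ori[c(j, i)]
          sc <- score_of(cand_ord, cand_ori)
          if (sc > cur + 1e-12) {
            ord <- cand_ord; ori <- cand_ori; cur <- sc
            improved <- TRUE
          }
          cand_ord <- ord; cand_ori <- ori
          cand_ord[i:j] <- rev(ord[i:j])
          cand_ori[i:j] <- rev(ifelse(ori[i:j] == "+", "-", "+"))
          sc <- score_of(cand_ord, cand_ori)
          if (sc > cur + 1e-12) {
            ord <- cand_ord; ori <- cand_ori; cur <- sc
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  list(order = ord, orientation = ori, score = cur)
}

subset_profiles <- function(profiles, contigs) {
  structure(list(abundance = profiles$abundance[contigs, , drop = FALSE],
                 centroid = profiles$centroid[contigs, , drop = FALSE],
                 lengths = profiles$lengths[contigs]),
            class = "repeat_profiles")
}

#' Find the best contig arrangement under the landmark objective
#'
#' `mode = "exhaustive"` enumerates every permutation and orientation
#' pattern (global optimum; allowed for at most 8 contigs).
#' `mode = "greedy"` inserts contigs in decreasing length order (ties broken
#' by contig name) at the best position and orientation.
#'
#' Contigs carrying a single landmark family have intrinsically ambiguous
#' orientation; they are flagged in the result.
#'
#' @param profiles A `repeat_profiles` object.
#' @param model A `landmark_model`.
#' @param mode `"exhaustive"` or `"greedy"`.
#' @return List with `order`, `orientation`, `score`, and
#'   `ambiguous_orientation` (contigs with at most one landmark family).
#' @export
best_order <- function(profiles, model, mode = c("greedy", "exhaustive")) {
  mode <- match.arg(mode)
  n <- nrow(profiles$abundance)
  if (n == 1) {
    res <- list(order = rownames(profiles$abundance), orientation = "+",
                score = 0)
  } else if (mode == "exhaustive") {
    if (n > 8) {
      stopf("exhaustive search is limited to 8 contigs (got %d); use mode = 'greedy'",
            n)
    }
    res <- exhaustive_order(profiles, model)
  } else {
    res <- greedy_order(profiles, model)
  }
  n_fam <- rowSums(profiles$abundance[res$order, , drop = FALSE] > 0)
  res$ambiguous_orientation <- res$order[n_fam <= 1]
  res
}

#' Write an arrangement as an AGP-like table
#'
#' @param arrangement Result of [best_order()].
#' @param profiles The `repeat_profiles` used for ordering (for lengths).
#' @param path Output TSV path.
#' @param object Name of the assembled pseudomolecule.
#' @return The path, invisibly.
#' @export
write_agp <- function(arrangement, profiles, path, object = "chrB") {
  lens <- profiles$lengths[arrangement$order]
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  tab <- data.frame(object = object,
                    object_start = starts, object_end = ends,
                    component = arrangement$order,
                    component_length = lens,
                    orientation = arrangement$orientation)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
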