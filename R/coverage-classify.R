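#' Coverage-based contig classification
#'
#' When a B chromosome is sequenced in a host background in which it is
#' present at higher copy number (here ~3 B copies per host genome
#' equivalent), per-contig mean read depth is bimodal: host contigs sit at
#' the 1x depth, B contigs at ~3x. A two-component lognormal mixture fitted
#' to per-contig mean depths yields a reproducible depth threshold for
#' assigning contigs to the B.
#'
#' @name coverage-classify
NULL

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Fit a two-component depth mixture
#'
#' `method = "em"` fits a two-component lognormal mixture (normal on
#' log-depth) by expectation-maximization with contigs weighted by length,
#' so that short noisy contigs do not dominate the fit. The classification
#' threshold is the depth of equal posterior membership between the two
#' components. `method = "kde-valley"` instead places the threshold at the
#' minimum of a kernel density estimate between the two highest modes.
#'
#' @param depths Data frame with columns `contig`, `length`, `mean_depth`.
#' @param method `"em"` or `"kde-valley"`.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return A list of class `mixture_fit`: `component_means` (named `low`,
#'   `high`, on the depth scale), `weights`, `threshold`, `method`,
#'   `converged`, `loglik` (length-weighted log-likelihood on the log-depth
#'   scale, `NA` for kde-valley), and log-scale parameters `mu`, `sigma`.
#'   `converged` is `FALSE` when the two components are closer than 1.5x or
#'   the data are degenerate; the fit is still returned.
#' @export
fit_depth_mixture <- function(depths, method = c("em", "kde-valley"),
                              max_iter = 500, tol = 1e-8) {
  method <- match.arg(method)
  if (nrow(depths) < 10) stopf("need >= 10 contigs to fit a depth mixture")
  if (any(depths$mean_depth < 0)) stopf("depths must be non-negative")
  pos <- depths$mean_depth > 0
  x <- log(depths$mean_depth[pos])
  w <- depths$length[pos]
  w <- w / mean(w)

  degenerate <- length(unique(x)) < 2
  if (degenerate) {
    m <- exp(x[1] %||% 0)
    out <- list(component_means = c(low = m, high = m),
                weights = c(0.5, 0.5), threshold = m, method = method,
                converged = FALSE, degenerate = TRUE, loglik = NA_real_,
                mu = c(x[1], x[1]), sigma = c(0, 0))
    class(out) <- "mixture_fit"
    return(out)
  }

  if (method == "em") {
    # initialize from the weighted median split
    med <- weighted_median(x, w)
    lo <- x <= med
    mu <- c(weighted.mean(x[lo], w[lo]), weighted.mean(x[!lo], w[!lo]))
    sigma <- rep(sqrt(max(1e-6, weighted.mean((x - mean(x))^2, w) / 4)), 2)
    lambda <- c(0.5, 0.5)
    ll_old <- -Inf
    converged_em <- FALSE
    for (iter in seq_len(max_iter)) {
      d1 <- lambda[1] * stats::dnorm(x, mu[1], sigma[1])
      d2 <- lambda[2] * stats::dnorm(x, mu[2], sigma[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      r <- d1 / tot
      ll <- sum(w * log(tot))
      if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
        converged_em <- TRUE
        break
      }
      ll_old <- ll
      w1 <- sum(w * r); w2 <- sum(w * (1 - r))
      lambda <- c(w1, w2) / (w1 + w2)
      mu <- c(sum(w * r * x) / w1, sum(w * (1 - r) * x) / w2)
      sigma <- sqrt(pmax(c(sum(w * r * (x - mu[1])^2) / w1,
                           sum(w * (1 - r) * (x - mu[2])^2) / w2), 1e-8))
    }
    if (mu[1] > mu[2]) {
      mu <- rev(mu); sigma <- rev(sigma); lambda <- rev(lambda)
    }
    means <- exp(mu + sigma^2 / 2)
    separated <- means[2] / means[1] >= 1.5
    thr <- em_threshold(mu, sigma, lambda)
    out <- list(component_means = c(low = means[1], high = means[2]),
                weights = lambda, threshold = thr, method = "em",
                converged = converged_em && separated, degenerate = FALSE,
                loglik = ll, mu = mu, sigma = sigma)
  } else {
    dens <- stats::density(x, weights = w / sum(w), bw = "SJ")
    dy <- dens$y
    modes <- which(diff(sign(diff(dy))) == -2) + 1L
    if (length(modes) < 2) {
      out <- list(component_means = c(low = exp(weighted.mean(x, w)),
                                      high = exp(weighted.mean(x, w))),
                  weights = c(0.5, 0.5),
                  threshold = exp(weighted.mean(x, w)),
                  method = "kde-valley", converged = FALSE,
                  degenerate = FALSE, loglik = NA_real_,
                  mu = rep(weighted.mean(x, w), 2), sigma = rep(NA_real_, 2))
    } else {
      top2 <- sort(modes[order(dy[modes], decreasing = TRUE)][1:2])
      valley <- top2[1] + which.min(dy[top2[1]:top2[2]]) - 1L
      means <- sort(exp(dens$x[top2]))
      thr <- exp(dens$x[valley])
      sep <- means[2] / means[1] >= 1.5
      out <- list(component_means = c(low = means[1], high = means[2]),
                  weights = c(NA_real_, NA_real_), threshold = thr,
                  method = "kde-valley", converged = sep, degenerate = FALSE,
                  loglik = NA_real_, mu = log(means), sigma = rep(NA_real_, 2))
    }
  }
  class(out) <- "mixture_fit"
  out
}

# Depth of equal posterior membership between two lognormal components:
# solve lambda1 N(t; mu1, s1) = lambda2 N(t; mu2, s2) on the log scale,
# taking the root between the component means.
em_threshold <- function(mu, sigma, lambda) {
  f <- function(t) {
    log(lambda[1]) + stats::dnorm(t, mu[1], sigma[1], log = TRUE) -
      log(lambda[2]) - stats::dnorm(t, mu[2], sigma[2], log = TRUE)
  }
  if (mu[2] - mu[1] < 1e-12) return(exp(mean(mu)))
  root <- tryCatch(
    stats::uniroot(f, lower = mu[1], upper = mu[2])$root,
    error = function(e) mean(mu)
  )
  exp(root)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit (%s): means %.2fx / %.2fx, threshold %.2fx, converged: %s\n",
              x$method, x$component_means[1], x$component_means[2],
              x$threshold, x$converged))
  invisible(x)
}

#' Assign contigs to host or B chromosome by depth threshold
#'
#' A contig is labeled `B` iff its mean depth strictly exceeds the
#' threshold; depth exactly at the threshold is labeled host (conservative
#' tie-break).
#'
#' @param depths Data frame `contig`, `length`, `mean_depth`.
#' @param threshold Depth threshold (> 0), e.g. from [fit_depth_mixture()].
#' @return Data frame `contig`, `label` (`"host"`/`"B"`), `mean_depth`.
#' @export
assign_contigs <- function(depths, threshold) {
  assert_scalar_number(threshold, "threshold")
  if (threshold <= 0) stopf("threshold must be > 0")
  data.frame(contig = depths$contig,
             label = ifelse(depths$mean_depth > threshold, "B", "host"),
             mean_depth = depths$mean_depth,
             stringsAsFactors = FALSE)
}

#' Summarize a host/B contig assignment
#'
#' @param labels Data frame from [assign_contigs()].
#' @param depths Data frame `contig`, `length`, `mean_depth` covering the
#'   same contigs.
#' @return List with per-class `n`, `total_length` and `mean_depth`, plus
#'   `depth_ratio` (`B / host`; `NA` with a note when a class is empty).
#' @export
summarize_assignment <- function(labels, depths) {
  m <- merge(labels[, c("contig", "label")], depths, by = "contig")
  if (nrow(m) != nrow(depths)) stopf("labels do not cover all contigs")
  per_class <- lapply(c(host = "host", B = "B"), function(cl) {
    sel <- m$label == cl
    list(n = sum(sel),
         total_length = sum(m$length[sel]),
         mean_depth = if (any(sel)) {
           weighted.mean(m$mean_depth[sel], m$length[sel])
         } else NA_real_)
  })
  ratio <- if (per_class$host$n == 0 || per_class$B$n == 0) {
    NA_real_
  } else {
    per_class$B$mean_depth / per_class$host$mean_depth
  }
  list(host = per_class$host, B = per_class$B, depth_ratio = ratio,
       note = if (is.na(ratio)) "ratio undefined: a class is empty" else NULL)
}

#' Read per-contig depths from TSV
#'
#' Expects columns `contig`, `length`, `mean_depth`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_contig_depths <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(c("contig", "length", "mean_depth"), names(tab))
  if (length(missing) > 0L) {
    stopf("contig depth table %s lacks columns: %s", path,
          paste(missing, collapse = ", "))
  }
  if (any(tab$length <= 0)) stopf("contig lengths must be positive")
  if (any(tab$mean_depth < 0)) stopf("mean depths must be non-negative")
  tab
}
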