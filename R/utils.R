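#' @importFrom stats median pnorm qnorm rnbinom rpois runif rmultinom
#'   var sd rlnorm cor p.adjust setNames weighted.mean density dnorm
#'   uniroot rgamma
#' @importFrom utils head tail write.table read.table modifyList
#' @importFrom methods is as
NULL

# round() in R rounds half to even; printed percentages in the source tables
# use conventional half-up rounding, so keep an explicit helper.
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("'%s' must be a single non-missing number", name)
  }
}

# Derive a reproducible child seed from a base seed and a stage label,
# keeping the result inside the 32-bit integer range R requires.
derive_seed <- function(seed, label) {
  h <- sum(as.integer(charToRaw(label)) * seq_along(charToRaw(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
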