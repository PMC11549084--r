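# shared fixture builders; all fixtures are generated in code

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, rate = 0.1) {
  v <- strsplit(s, "")[[1]]
  i <- sample(length(v), round(rate * length(v)))
  v[i] <- sample(c("A", "C", "G", "T"), length(i), replace = TRUE)
  paste(v, collapse = "")
}

# a small reference genome reused across tests (built once per run)
small_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_genome(genome_spec(), seed = 7L)
    cache
  }
})

# two-group null design for calibration experiments
null_design <- function(replicates = 3) {
  data.frame(sample = paste0("s", seq_len(2 * replicates)),
             group = rep(c("g1", "g2"), each = replicates),
             stringsAsFactors = FALSE)
}
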