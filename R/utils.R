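#' @importFrom stats median quantile rnorm runif rbinom rlnorm rbeta
#'   pnorm optim setNames
#' @importFrom utils write.table read.table head combn
NULL

# truncated Gaussian draw on [lo, hi] by rejection with clamp fallback
rnorm_trunc <- function(n, mean = 0, sd = 1, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  for (i in seq_len(25)) {
    if (!length(bad)) break
    x[bad] <- rnorm(length(bad), mean[pmin(bad, length(mean))], sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  pmin(pmax(x, lo), hi)
}

#' Derive a reproducible child seed from a master seed
#'
#' Used to give each stochastic pipeline stage (fragmentation, hybridization
#' noise, replicates) an independent but reproducible stream.
#'
#' @param seed Integer master seed.
#' @param offset Integer stage offset.
#' @return An integer seed below 2^31.
#' @keywords internal
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483587L)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# write a data.frame as plain TSV (no quoting, no row names)
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
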