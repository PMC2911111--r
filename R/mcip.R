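#' Salt steps of the MCIp elution series, in mM NaCl
#' @export
MCIP_SALT_STEPS <- c(250L, 300L, 350L, 400L, 450L, 500L, 1000L)

#' Affinity parameters of the salt-elution model
#'
#' The expected elution step index of a fragment is a logistic function
#' of its methylated-CpG load m:
#' \deqn{E[idx] = 1 + 6 / (1 + e^{-slope (m - midpoint)})}
#' mapped onto the seven salt steps 250..1,000 mM. The realised step is
#' the rounded expectation, shifted by one step up or down with
#' probability \code{p_shift}/2 each (elution is stochastic). Monotone in
#' m by construction: a densely methylated fragment elutes at high salt,
#' an unmethylated one in the low-salt steps.
#'
#' @param midpoint Methylated-CpG count at which a fragment is equally
#'   likely to sit in the lower or upper half of the series.
#' @param slope Logistic slope per methylated CpG.
#' @param p_shift Total probability of a one-step assignment shift.
#' @return A list of class \code{affinity_params}.
#' @export
affinity_params <- function(midpoint = 3.5, slope = 1.2, p_shift = 0.1) {
  stopifnot(slope > 0, p_shift >= 0, p_shift < 1)
  structure(list(midpoint = midpoint, slope = slope, p_shift = p_shift),
            class = "affinity_params")
}

#' Sonicate the genome into fragments carrying per-molecule methylation
#'
#' Fragment starts are uniform over each chromosome, lengths are
#' truncated Gaussian around \code{mean_len}. Each fragment samples its
#' methylated-CpG count by an independent Bernoulli draw per overlapped
#' CpG with that site's population methylation fraction for the given
#' state and time (molecules are independent across CpGs).
#'
#' @param genome A \code{GenomeModel}.
#' @param methylome A \code{MethylomeState}.
#' @param state Cell state the pool of molecules comes from.
#' @param time_h Time point in hours.
#' @param mean_len,sd_len Fragment length distribution, bp (sonication
#'   to a mean size of 350-400 bp; default 375 +/- 50).
#' @param coverage Mean number of fragments covering a genomic position.
#' @param seed Integer seed.
#' @return data.frame of class \code{FragmentSet}: chrom, start, end,
#'   state, time_h, n_cpg, n_mcpg.
#' @export
fragment_genome <- function(genome, methylome, state = "DC", time_h = 168,
                            mean_len = 375, sd_len = 50, coverage = 30,
                            seed = 1L) {
  stopifnot(coverage > 0, mean_len > 0)
  if (!length(genome$seqs)) stop_config("empty genome")
  set.seed(seed)
  frac <- methylation_fraction(methylome, state, time_h)
  site_gr <- GenomicRanges::GRanges(methylome$sites$chrom,
    IRanges::IRanges(methylome$sites$pos + 1L, width = 2L))
  out <- list()
  for (ch in names(genome$seqs)) {
    len <- length(genome$seqs[[ch]])
    nfrag <- round(coverage * len / mean_len)
    flen <- round(rnorm_trunc(nfrag, mean_len, sd_len, 100, mean_len + 6 * sd_len))
    start <- floor(runif(nfrag, 0, len - flen))
    out[[ch]] <- data.frame(chrom = ch, start = as.integer(start),
                            end = as.integer(start + flen),
                            stringsAsFactors = FALSE)
  }
  fr <- do.call(rbind, out)
  rownames(fr) <- NULL
  fr$state <- state
  fr$time_h <- time_h
  fgr <- GenomicRanges::GRanges(fr$chrom, IRanges::IRanges(fr$start + 1L, fr$end))
  hits <- GenomicRanges::findOverlaps(fgr, site_gr, type = "any",
                                      minoverlap = 2L)
  fr$n_cpg <- 0L
  cnt <- table(S4Vectors::queryHits(hits))
  fr$n_cpg[as.integer(names(cnt))] <- as.integer(cnt)
  draws <- rbinom(length(hits), 1L, frac[S4Vectors::subjectHits(hits)])
  fr$n_mcpg <- 0L
  msum <- tapply(draws, S4Vectors::queryHits(hits), sum)
  fr$n_mcpg[as.integer(names(msum))] <- as.integer(msum)
  class(fr) <- c("FragmentSet", "data.frame")
  fr
}

#' Assign a salt-elution step to fragments
#'
#' @param n_mcpg Integer vector of methylated-CpG counts.
#' @param params An [affinity_params()] list.
#' @return Integer vector of salt concentrations (mM), one of
#'   \code{MCIP_SALT_STEPS}.
#' @export
elute_fragment <- function(n_mcpg, params = affinity_params()) {
  expected <- 1 + 6 / (1 + exp(-params$slope * (n_mcpg - params$midpoint)))
  # stochastic rounding keeps the mean step strictly increasing in the
  # methylated-CpG load even between counts that round alike
  idx <- floor(expected) + (runif(length(n_mcpg)) < expected %% 1)
  u <- runif(length(n_mcpg))
  idx <- idx + (u < params$p_shift / 2) - (u > 1 - params$p_shift / 2)
  idx <- pmin(pmax(idx, 1L), 7L)
  MCIP_SALT_STEPS[idx]
}

#' Elute a fragment set into the salt-step series
#'
#' @param fragments A \code{FragmentSet}.
#' @param params An [affinity_params()] list.
#' @param seed Integer seed.
#' @return An \code{ElutionProfile}: the fragment table with a
#'   \code{salt_mM} column plus the per-step fragment counts.
#' @export
elute_fragments <- function(fragments, params = affinity_params(), seed = 1L) {
  set.seed(seed)
  fragments$salt_mM <- elute_fragment(fragments$n_mcpg, params)
  counts <- table(factor(fragments$salt_mM, levels = MCIP_SALT_STEPS))
  structure(list(fragments = fragments,
                 steps = MCIP_SALT_STEPS,
                 step_counts = as.integer(counts)),
            class = "ElutionProfile")
}

#' Pool elution fractions into the CpG and mCpG pools
#'
#' Fractions at 250-350 mM NaCl (unmethylated DNA) form the CpG pool;
#' fractions at 400-1,000 mM (methylated DNA) form the mCpG pool. The
#' partition is exhaustive and disjoint.
#'
#' @param profile An \code{ElutionProfile}.
#' @return A \code{PoolAssignment}: the fragment table with a
#'   \code{pool} factor in {CpG, mCpG}.
#' @export
pool_fractions <- function(profile) {
  fr <- profile$fragments
  if (any(is.na(fr$salt_mM)))
    stop_config("fragments without an elution step cannot be pooled")
  fr$pool <- factor(ifelse(fr$salt_mM <= 350L, "CpG", "mCpG"),
                    levels = c("CpG", "mCpG"))
  class(fr) <- c("PoolAssignment", "data.frame")
  fr
}

#' Per-interval pool abundance
#'
#' Counts fragments of each pool overlapping each query interval; the
#' quantity hybridized to a probe is proportional to this count.
#'
#' @param pools A \code{PoolAssignment}.
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @return The intervals with \code{n_CpG_pool} and \code{n_mCpG_pool}
#'   columns appended.
#' @export
pool_abundance <- function(pools, intervals) {
  lev <- sort(unique(c(intervals$chrom, pools$chrom)))
  igr <- GenomicRanges::GRanges(factor(intervals$chrom, levels = lev),
                                IRanges::IRanges(intervals$start + 1L,
                                                 intervals$end))
  for (p in c("CpG", "mCpG")) {
    sub <- pools[pools$pool == p, , drop = FALSE]
    pgr <- GenomicRanges::GRanges(factor(sub$chrom, levels = lev),
                                  IRanges::IRanges(sub$start + 1L, sub$end))
    intervals[[paste0("n_", p, "_pool")]] <-
      GenomicRanges::countOverlaps(igr, pgr)
  }
  intervals
}

#' Recovery of control regions from the two pools
#'
#' Mirrors the qPCR fractionation control: a CpG-free region ("Empty")
#' must recover in the unmethylated pool, an imprinted-like region at 50%
#' population methylation should split between pools.
#'
#' @param pools A \code{PoolAssignment}.
#' @param control_regions data.frame with region_id, chrom, start, end.
#' @param genome Optional \code{GenomeModel} used to verify that control
#'   coordinates exist in the genome.
#' @return data.frame with per-region fragment counts and pool fractions.
#' @export
control_recovery <- function(pools, control_regions, genome = NULL) {
  if (!is.null(genome)) {
    for (i in seq_len(nrow(control_regions))) {
      ch <- control_regions$chrom[i]
      if (!ch %in% names(genome$seqs) ||
          control_regions$end[i] > length(genome$seqs[[ch]]) ||
          control_regions$start[i] < 0)
        stop_config("control region %s is absent from the genome",
                    control_regions$region_id[i])
    }
  }
  ab <- pool_abundance(pools, control_regions)
  ab$n_total <- ab$n_CpG_pool + ab$n_mCpG_pool
  ab$frac_CpG_pool <- ifelse(ab$n_total > 0, ab$n_CpG_pool / ab$n_total, NA)
  ab$frac_mCpG_pool <- ifelse(ab$n_total > 0, ab$n_mCpG_pool / ab$n_total, NA)
  ab
}

#' Write a pooled fragment table as TSV
#' @param pools A \code{PoolAssignment}.
#' @param path Output path.
#' @export
write_fragments_tsv <- function(pools, path) {
  write_tsv(as.data.frame(pools), path)
}
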