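#' Anchored logistic demethylation curve
#'
#' Population methylation fraction of a CpG in the dendritic-cell lineage
#' as a function of time since the onset of differentiation. The curve is
#' a logistic decay from \code{initial} to \code{final} with midpoint at
#' \code{onset} hours and slope \code{steepness} (per hour), rescaled so
#' that the value at t = 0 equals \code{initial} exactly:
#' \deqn{f(t) = final + (initial - final)\frac{1 + e^{-s\,onset}}{1 + e^{s(t - onset)}}}
#' For onsets of 18 h or later at the default steepness the rescaling
#' factor is within 0.5% of 1, so f(onset) is the midpoint
#' (initial + final)/2 to that accuracy. A flat CpG (initial == final)
#' returns \code{initial} at every time.
#'
#' @param t Time(s) in hours, non-negative.
#' @param initial,final Start and asymptotic end fractions in [0, 1].
#' @param onset Midpoint of the decay in hours.
#' @param steepness Logistic slope per hour (default 0.3).
#' @return Methylation fraction(s) in [0, 1]; monotone non-increasing in t.
#' @export
demethylation_curve <- function(t, initial, final, onset, steepness = 0.3) {
  n <- max(length(t), length(initial), length(final), length(onset),
           length(steepness))
  t <- rep_len(t, n); initial <- rep_len(initial, n)
  final <- rep_len(final, n); onset <- rep_len(onset, n)
  steepness <- rep_len(steepness, n)
  flat <- is.na(onset) | initial == final
  val <- initial
  if (any(!flat)) {
    i <- which(!flat)
    anchor <- 1 + exp(-steepness[i] * onset[i])
    v <- final[i] + (initial[i] - final[i]) * anchor /
      (1 + exp(steepness[i] * (t[i] - onset[i])))
    val[i] <- pmin(pmax(v, 0), 1)
  }
  val
}

#' Configuration for methylome planting
#'
#' @param dmr_width Width of planted DMRs in bp.
#' @param min_dmr_cpgs Minimum CpGs a candidate DMR window must contain.
#' @param meth_high,meth_low "Methylated" / "demethylated" population
#'   fraction thresholds; planted DMR CpGs start at or above
#'   \code{meth_high} in monocytes and fall to or below \code{meth_low}
#'   in dendritic cells by day 7 (168 h).
#' @param p_early Probability a DMR belongs to the early kinetics class.
#' @param early_range Onset window (h) of early-demethylating CpGs.
#' @param late_range Onset window (h) of late-demethylating CpGs.
#' @param steepness Logistic slope of the decay, per hour.
#' @param state_noise_sd SD of the additive truncated-Gaussian offset
#'   between cell states at non-differential CpGs (population fraction).
#' @param onset_jitter Per-CpG onset jitter around the DMR onset, h.
#' @param domain_width Width of the methylation domains over which the
#'   flat baseline is drawn, bp; neighbouring CpGs share a domain
#'   baseline because methylation is regionally coherent.
#' @param domain_jitter_sd Per-CpG jitter around the domain baseline.
#' @return A list of class \code{methylome_config}.
#' @export
methylome_config <- function(dmr_width = 600L,
                             min_dmr_cpgs = 8L,
                             meth_high = 0.8,
                             meth_low = 0.2,
                             p_early = 0.5,
                             early_range = c(18, 42),
                             late_range = c(51, 120),
                             steepness = 0.3,
                             state_noise_sd = 0.02,
                             onset_jitter = 3,
                             domain_width = 2000L,
                             domain_jitter_sd = 0.05) {
  structure(as.list(environment()), class = "methylome_config")
}

#' Plant a three-state methylome with DC-specific demethylation events
#'
#' Assigns every CpG of the genome a population methylation fraction for
#' monocytes (MO), macrophages (MAC) and dendritic cells (DC). Exactly
#' \code{n_dmrs} regions are planted as differentially methylated:
#' methylated in MO and MAC (fraction >= \code{meth_high}) and actively
#' demethylated along the DC lineage to <= \code{meth_low} by 168 h, with
#' a locus-specific logistic onset drawn from an early ([18, 42] h) or
#' late ((51 h, ...]) kinetics class. All other CpGs are flat in time and
#' differ between states only by a truncated-Gaussian offset clamped so
#' that no state at any time exceeds the monocyte baseline: the model
#' contains no de novo methylation by construction.
#'
#' @param genome A \code{GenomeModel}.
#' @param n_dmrs Number of DMRs to plant.
#' @param dmr_position_mix Named proportions (summing to 1) of
#'   \code{proximal}, \code{intragenic} and \code{intergenic} DMR
#'   placements relative to gene annotation.
#' @param seed Integer seed.
#' @param config A [methylome_config()].
#' @return An object of class \code{MethylomeState}: list with
#'   \code{sites} (per-CpG kinetics parameters and state offsets),
#'   \code{dmrs} (the planted-DMR registry) and \code{config}.
#' @export
plant_methylome <- function(genome, n_dmrs = 10L,
                            dmr_position_mix = c(proximal = 0.4,
                                                 intragenic = 0.3,
                                                 intergenic = 0.3),
                            seed = 1L,
                            config = methylome_config()) {
  stopifnot(n_dmrs >= 0)
  if (abs(sum(dmr_position_mix) - 1) > 1e-8)
    stop_config("dmr_position_mix must sum to 1")
  set.seed(seed)
  cfg <- config
  sites <- cpg_sites(genome)
  n <- nrow(sites)
  if (!n) stop_config("genome contains no CpG sites")

  # flat baseline: methylation is regionally coherent, so the
  # bimodal-with-shoulder mixture typical of promoter methylomes is
  # drawn per ~2-kb domain and jittered per CpG
  domain <- paste(sites$chrom, sites$pos %/% cfg$domain_width)
  doms <- unique(domain)
  comp <- sample.int(3L, length(doms), replace = TRUE,
                     prob = c(0.45, 0.45, 0.10))
  dbase <- numeric(length(doms))
  dbase[comp == 1L] <- rbeta(sum(comp == 1L), 1.5, 10)   # unmethylated
  dbase[comp == 2L] <- rbeta(sum(comp == 2L), 10, 1.5)   # methylated
  dbase[comp == 3L] <- rbeta(sum(comp == 3L), 2, 2)      # intermediate
  base <- dbase[match(domain, doms)] +
    rnorm_trunc(n, 0, cfg$domain_jitter_sd,
                -2 * cfg$domain_jitter_sd, 2 * cfg$domain_jitter_sd)
  base <- pmin(pmax(base, 0.02), 0.98)

  sites$initial <- base
  sites$final <- base
  sites$onset <- NA_real_
  sites$steepness <- cfg$steepness
  sites$is_dmr <- FALSE
  sites$dmr_id <- NA_character_

  dmrs <- choose_dmr_regions(genome, sites, n_dmrs, dmr_position_mix, cfg)

  if (n_dmrs > 0) {
    dmrs$kinetics_class <- ifelse(runif(n_dmrs) < cfg$p_early, "early", "late")
    for (i in seq_len(n_dmrs)) {
      idx <- which(sites$chrom == dmrs$chrom[i] &
                   sites$pos >= dmrs$start[i] & sites$pos < dmrs$end[i])
      rng <- if (dmrs$kinetics_class[i] == "early") cfg$early_range else cfg$late_range
      dmr_onset <- runif(1, rng[1], rng[2])
      sites$is_dmr[idx] <- TRUE
      sites$dmr_id[idx] <- dmrs$dmr_id[i]
      # keep MO *and* noise-offset MAC fractions above meth_high
      sites$initial[idx] <- runif(length(idx),
                                  cfg$meth_high + 3 * cfg$state_noise_sd + 0.01,
                                  0.95)
      sites$final[idx] <- runif(length(idx), 0.05, cfg$meth_low - 0.05)
      sites$onset[idx] <- pmin(pmax(dmr_onset +
        runif(length(idx), -cfg$onset_jitter, cfg$onset_jitter), rng[1]), rng[2])
      dmrs$onset_h[i] <- dmr_onset
      dmrs$n_cpg[i] <- length(idx)
    }
  }

  # state offsets: truncated Gaussian, clamped so no fraction ever
  # exceeds the monocyte (t = 0) baseline -> no de novo methylation
  sites$mac_offset <- pmin(rnorm_trunc(n, 0, cfg$state_noise_sd,
                                       -3 * cfg$state_noise_sd,
                                       3 * cfg$state_noise_sd), 0)
  sites$dc_offset <- pmin(rnorm_trunc(n, 0, cfg$state_noise_sd,
                                      -3 * cfg$state_noise_sd,
                                      3 * cfg$state_noise_sd), 0)

  structure(list(sites = sites, dmrs = dmrs, config = cfg, seed = seed),
            class = "MethylomeState")
}

# pick n_dmrs non-overlapping windows matching the positional mix
choose_dmr_regions <- function(genome, sites, n_dmrs, mix, cfg) {
  empty <- data.frame(dmr_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      position_class = character(0), direction = character(0),
                      kinetics_class = character(0), onset_h = numeric(0),
                      n_cpg = integer(0), stringsAsFactors = FALSE)
  if (n_dmrs == 0) return(empty)
  classes <- c("proximal", "intragenic", "intergenic")
  counts <- floor(mix[classes] * n_dmrs)
  while (sum(counts) < n_dmrs)
    counts[which.max(mix[classes] * n_dmrs - counts)] <-
      counts[which.max(mix[classes] * n_dmrs - counts)] + 1L

  g <- genome$genes
  if (!nrow(g) && (counts["proximal"] > 0 || counts["intragenic"] > 0))
    stop_config("cannot place proximal/intragenic DMRs in a genome without genes")
  half <- cfg$dmr_width %/% 2L
  chosen <- empty
  taken <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  gene_order <- sample(nrow(g))
  gi <- 1L
  for (cls in classes) {
    need <- counts[[cls]]
    tries <- 0L
    max_tries <- 200L * (counts[[cls]] + 1L)
    while (need > 0L) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop_config("unable to place %d %s DMRs with >= %d CpGs each",
                    counts[[cls]], cls, cfg$min_dmr_cpgs)
      center <- propose_dmr_center(genome, g, cls, gene_order, gi, cfg)
      gi <- gi %% max(1L, nrow(g)) + 1L
      if (is.null(center)) next
      st <- center$pos - half; en <- center$pos + half
      len <- length(genome$seqs[[center$chrom]])
      if (st < 0L || en > len) next
      if (nrow(taken) && any(taken$chrom == center$chrom &
                             st < taken$end + 2000L &
                             en > taken$start - 2000L)) next
      ncp <- sum(sites$chrom == center$chrom & sites$pos >= st & sites$pos < en)
      if (ncp < cfg$min_dmr_cpgs) next
      taken <- rbind(taken, data.frame(chrom = center$chrom,
                                       start = as.integer(st),
                                       end = as.integer(en),
                                       stringsAsFactors = FALSE))
      chosen <- rbind(chosen, data.frame(
        dmr_id = sprintf("dmr%03d", nrow(chosen) + 1L),
        chrom = center$chrom, start = as.integer(st), end = as.integer(en),
        position_class = cls, direction = "hypomethylated-in-DC",
        kinetics_class = NA_character_, onset_h = NA_real_, n_cpg = ncp,
        stringsAsFactors = FALSE))
      need <- need - 1L
    }
  }
  chosen[sample(nrow(chosen)), , drop = FALSE]
}

# candidate DMR midpoint for a positional class, in 0-based coordinates.
# Proximal DMRs sit inside promoter windows; intragenic and intergenic
# DMRs are proposed at the genome's dispersed CpG clusters, since a
# region without clustered CpGs cannot be differentially methylated.
propose_dmr_center <- function(genome, g, cls, gene_order, gi, cfg) {
  if (cls == "proximal") {
    row <- g[gene_order[gi], ]
    dirn <- if (row$strand == "+") 1L else -1L
    off <- sample(seq(-600L, 600L), 1L)
    pos <- row$tss + dirn * off
    return(list(chrom = row$chrom, pos = as.integer(pos)))
  }
  cl <- genome$cpg_clusters
  if (is.null(cl) || !nrow(cl)) return(NULL)
  mids <- (cl$start + cl$end) %/% 2L
  keep <- logical(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    gch <- g[g$chrom == cl$chrom[i], ]
    near_tss <- nrow(gch) && any(abs(mids[i] - gch$tss) <= 1200L)
    in_body <- nrow(gch) && any(mids[i] >= gch$start & mids[i] < gch$end)
    keep[i] <- if (cls == "intragenic") in_body && !near_tss
               else !in_body && !near_tss
  }
  if (!any(keep)) return(NULL)
  j <- sample(which(keep), 1L)
  list(chrom = cl$chrom[j], pos = as.integer(mids[j]))
}

#' Population methylation fractions at one state and time
#'
#' @param methylome A \code{MethylomeState}.
#' @param state One of "MO", "MAC", "DC".
#' @param time_h Time in hours (MO and MAC are constant in time; DC
#'   follows the per-CpG demethylation curve).
#' @return Numeric vector of fractions aligned with
#'   \code{methylome$sites} rows.
#' @export
methylation_fraction <- function(methylome, state = c("MO", "MAC", "DC"),
                                 time_h = 0) {
  state <- match.arg(state)
  s <- methylome$sites
  if (state == "MO") return(s$initial)
  if (state == "MAC") return(pmax(pmin(s$initial + s$mac_offset, s$initial), 0))
  top <- pmax(pmin(s$initial + s$dc_offset, s$initial), 0)
  fin <- pmin(s$final, top)
  demethylation_curve(time_h, top, fin, s$onset, s$steepness)
}

#' Sample the methylome time course as a long table
#'
#' @param methylome A \code{MethylomeState}.
#' @param times Sorted non-negative hours.
#' @param states Cell states to include.
#' @return data.frame with columns chrom, pos, state, time_h, fraction.
#' @export
sample_timecourse <- function(methylome, times = c(0, 6, 18, 30, 42, 51, 66, 168),
                              states = c("MO", "MAC", "DC")) {
  stopifnot(!is.unsorted(times), all(times >= 0))
  out <- list()
  for (st in states) {
    ts <- if (st == "MO") 0 else times
    for (t in ts) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = methylome$sites$chrom, pos = methylome$sites$pos,
        state = st, time_h = t,
        fraction = methylation_fraction(methylome, st, t),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write / read the planted-DMR registry as BED6
#'
#' The BED name field encodes \code{dmr_id|position_class|kinetics_class|
#' direction} so the registry round-trips through the file.
#'
#' @param dmrs The \code{dmrs} data.frame of a \code{MethylomeState}.
#' @param path Output path.
#' @return The path (writer) or the reconstructed data.frame (reader).
#' @export
write_dmr_bed <- function(dmrs, path) {
  gr <- GenomicRanges::GRanges(dmrs$chrom,
                               IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  gr$name <- paste(dmrs$dmr_id, dmrs$position_class, dmrs$kinetics_class,
                   dmrs$direction, sep = "|")
  gr$score <- dmrs$n_cpg
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_dmr_bed
#' @export
read_dmr_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  f <- do.call(rbind, strsplit(gr$name, "|", fixed = TRUE))
  data.frame(dmr_id = f[, 1],
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             position_class = f[, 2], kinetics_class = f[, 3],
             direction = f[, 4], n_cpg = as.integer(gr$score),
             stringsAsFactors = FALSE)
}

#' Write a sampled methylation table as TSV
#' @param tab Output of [sample_timecourse()].
#' @param path Output path.
#' @export
write_methylation_tsv <- function(tab, path) write_tsv(tab, path)
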