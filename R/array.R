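#' Design promoter tiling probes
#'
#' Tiles each strand-aware promoter window (-promoter_up..+promoter_down
#' bp around the TSS, both endpoints included) at fixed spacing, plus any
#' extra regions tiled over larger genomic intervals (the custom array
#' contained a small number of such regions in addition to the ~17,000
#' promoters). Windows extending past chromosome ends are clipped.
#'
#' @param genome A \code{GenomeModel}.
#' @param spacing Probe start-to-start spacing, bp.
#' @param probe_len Probe length, bp.
#' @param extra_regions Optional data.frame (chrom, start, end, region_id)
#'   of additional tiled intervals.
#' @return A \code{ProbeSet} data.frame: probe_id, chrom, start, end,
#'   tile_id, gene_id, probe_rank (order within its tile), gc_fraction.
#' @export
design_probes <- function(genome, spacing = 200L, probe_len = 50L,
                          extra_regions = NULL) {
  stopifnot(spacing > 0, probe_len > 0)
  cfg <- genome$config
  g <- genome$genes
  rows <- list()
  for (i in seq_len(nrow(g))) {
    len <- length(genome$seqs[[g$chrom[i]]])
    dirn <- if (g$strand[i] == "+") 1L else -1L
    offsets <- seq.int(-cfg$promoter_up, cfg$promoter_down, by = spacing)
    starts <- g$tss[i] + dirn * offsets
    starts <- sort(starts)
    keep <- starts >= 0L & (starts + probe_len) <= len
    if (!all(keep))
      message(sprintf("probe window of %s clipped at chromosome end", g$gene_id[i]))
    starts <- starts[keep]
    if (!length(starts)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom[i], start = starts, end = starts + probe_len,
      tile_id = g$gene_id[i], gene_id = g$gene_id[i],
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(NROW(extra_regions))) {
    r <- extra_regions[j, ]
    len <- length(genome$seqs[[r$chrom]])
    starts <- seq.int(r$start, max(r$start, r$end - probe_len), by = spacing)
    starts <- starts[starts >= 0L & starts + probe_len <= len]
    if (!length(starts)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = r$chrom, start = as.integer(starts),
      end = as.integer(starts + probe_len),
      tile_id = as.character(r$region_id), gene_id = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop_config("no probes could be designed")
  probes <- do.call(rbind, rows)
  probes <- probes[order(probes$tile_id, probes$chrom, probes$start), ]
  rownames(probes) <- NULL
  probes$probe_rank <- stats::ave(seq_len(nrow(probes)), probes$tile_id,
                                  FUN = seq_along)
  probes$probe_id <- sprintf("p%06d", seq_len(nrow(probes)))
  probes$gc_fraction <- vapply(seq_len(nrow(probes)), function(i) {
    s <- genome_window_seq(genome, probes$chrom[i], probes$start[i],
                           probes$end[i])
    gc_fraction(s)
  }, numeric(1))
  class(probes) <- c("ProbeSet", "data.frame")
  probes
}

#' Hybridization noise parameters
#'
#' @param gain Intensity units per overlapping fragment.
#' @param background Background intensity (fragment-equivalents) added to
#'   every probe.
#' @param sdlog SD of the multiplicative lognormal probe noise.
#' @param dye_bias Multiplicative bias of the DC channel relative to the
#'   MAC channel (removed by linear normalization).
#' @return A list of class \code{hyb_params}.
#' @export
hyb_params <- function(gain = 100, background = 2, sdlog = 0.1,
                       dye_bias = 1.3) {
  structure(list(gain = gain, background = background, sdlog = sdlog,
                 dye_bias = dye_bias), class = "hyb_params")
}

#' Simulate one dual reciprocal hybridization
#'
#' Two two-channel arrays: the CpG (unmethylated) pools of DC and MAC
#' co-hybridized on one array, the mCpG (methylated) pools on the other.
#' Expected probe intensity is proportional to the number of pool
#' fragments overlapping the probe plus additive background, with
#' multiplicative lognormal noise and a configurable dye bias on the DC
#' channel.
#'
#' @param pools_dc,pools_mac \code{PoolAssignment} objects for the two
#'   cell states.
#' @param probes A \code{ProbeSet}.
#' @param params A [hyb_params()] list.
#' @param seed Integer seed.
#' @param replicate Replicate label stored in the output.
#' @return A \code{MirrorSignal} data.frame: probe metadata plus raw
#'   intensities dc_cpg, mac_cpg, dc_mcpg, mac_mcpg.
#' @export
simulate_hybridization <- function(pools_dc, pools_mac, probes,
                                   params = hyb_params(), seed = 1L,
                                   replicate = 1L) {
  set.seed(seed)
  ab_dc <- pool_abundance(pools_dc, probes[, c("chrom", "start", "end")])
  ab_mac <- pool_abundance(pools_mac, probes[, c("chrom", "start", "end")])
  n <- nrow(probes)
  noisy <- function(abund, dye) {
    params$gain * (abund + params$background) * dye *
      rlnorm(n, meanlog = -params$sdlog^2 / 2, sdlog = params$sdlog)
  }
  sig <- probes[, c("probe_id", "chrom", "start", "end", "tile_id",
                    "gene_id", "probe_rank")]
  sig$replicate <- as.integer(replicate)
  sig$dc_cpg <- noisy(ab_dc$n_CpG_pool, params$dye_bias)
  sig$mac_cpg <- noisy(ab_mac$n_CpG_pool, 1)
  sig$dc_mcpg <- noisy(ab_dc$n_mCpG_pool, params$dye_bias)
  sig$mac_mcpg <- noisy(ab_mac$n_mCpG_pool, 1)
  class(sig) <- c("MirrorSignal", "data.frame")
  sig
}

#' Linear (median-scaling) channel normalization
#'
#' Within each of the two hybridizations, each channel is divided by a
#' single factor so that the channel medians are equal (their geometric
#' mean), the linear normalization of a standard comparative genomic
#' hybridization protocol. Scaling is monotone and rank-preserving.
#'
#' @param signal A raw \code{MirrorSignal}.
#' @return The signal with normalized intensities.
#' @export
normalize_channels <- function(signal) {
  norm_pair <- function(a, b) {
    ma <- median(a); mb <- median(b)
    if (ma <= 0 || mb <= 0) stop_config("cannot normalize an all-zero channel")
    target <- sqrt(ma * mb)
    list(a * target / ma, b * target / mb)
  }
  for (rep in unique(signal$replicate)) {
    i <- signal$replicate == rep
    p <- norm_pair(signal$dc_cpg[i], signal$mac_cpg[i])
    signal$dc_cpg[i] <- p[[1]]; signal$mac_cpg[i] <- p[[2]]
    p <- norm_pair(signal$dc_mcpg[i], signal$mac_mcpg[i])
    signal$dc_mcpg[i] <- p[[1]]; signal$mac_mcpg[i] <- p[[2]]
  }
  signal
}

#' Flag probes with abnormal hybridization behaviour
#'
#' A probe is flagged if any of its four channel intensities falls below
#' the \code{low_q} or above the \code{high_q} empirical quantile of that
#' channel (within its replicate). Flagged probes are excluded from
#' scoring and DMR calling.
#'
#' @param signal A \code{MirrorSignal}.
#' @param low_q,high_q Quantile bounds, 0 <= low_q < high_q <= 1.
#' @return The signal with a logical \code{flagged} column.
#' @export
filter_probes <- function(signal, low_q = 0.001, high_q = 0.999) {
  stopifnot(low_q >= 0, high_q <= 1, low_q < high_q)
  signal$flagged <- FALSE
  chans <- c("dc_cpg", "mac_cpg", "dc_mcpg", "mac_mcpg")
  for (rep in unique(signal$replicate)) {
    i <- which(signal$replicate == rep)
    for (ch in chans) {
      x <- signal[[ch]][i]
      qs <- quantile(x, c(low_q, high_q), names = FALSE, type = 7)
      signal$flagged[i] <- signal$flagged[i] | x < qs[1] | x > qs[2]
    }
  }
  signal
}

#' The mirror-image DMR statistic
#'
#' For each unflagged probe computes the two log10 ratios
#' r_CpG = log10(DC/MAC) on the unmethylated-pool array and
#' r_mCpG = log10(DC/MAC) on the methylated-pool array, and their
#' difference s = r_CpG - r_mCpG. A genuine methylation difference shows
#' reciprocal behaviour — enrichment in one pool mirrored by depletion in
#' the other — so it adds in s, while copy-number-like shifts that move
#' both ratios together cancel. Positive s marks hypomethylation in DC.
#'
#' @param signal A normalized, filtered \code{MirrorSignal}.
#' @param floor Positive intensity floor applied before taking logs.
#' @return The signal with r_cpg, r_mcpg and score columns; flagged
#'   probes carry NA scores.
#' @export
mirror_score <- function(signal, floor = 1e-6) {
  clip <- function(x) pmax(x, floor)
  signal$r_cpg <- log10(clip(signal$dc_cpg) / clip(signal$mac_cpg))
  signal$r_mcpg <- log10(clip(signal$dc_mcpg) / clip(signal$mac_mcpg))
  signal$score <- signal$r_cpg - signal$r_mcpg
  if (!is.null(signal$flagged)) {
    signal$r_cpg[signal$flagged] <- NA_real_
    signal$r_mcpg[signal$flagged] <- NA_real_
    signal$score[signal$flagged] <- NA_real_
  }
  signal
}

#' Call DMRs from two biological replicates
#'
#' A region is called when at least \code{min_probes} consecutive
#' unflagged probes of the same tile exceed the score threshold with a
#' consistent sign in BOTH replicates (intersection of the qualifying
#' probe sets, not score averaging). Direction follows the sign:
#' positive scores mean hypomethylated in DC.
#'
#' @param signal A scored \code{MirrorSignal} holding both replicates.
#' @param threshold Minimum |s| per probe.
#' @param min_probes Minimum run length of qualifying probes.
#' @return A \code{DMRCall} data.frame: region coords, direction,
#'   mean_score, n_probes, replicate_support, central probe metadata.
#' @export
call_dmrs <- function(signal, threshold = 0.6, min_probes = 2L) {
  stopifnot(threshold > 0, min_probes >= 1)
  reps <- sort(unique(signal$replicate))
  if (length(reps) != 2L)
    stop_config("expected exactly 2 replicates, found %d", length(reps))
  a <- signal[signal$replicate == reps[1], ]
  b <- signal[signal$replicate == reps[2], ]
  a <- a[order(a$probe_id), ]; b <- b[order(b$probe_id), ]
  if (!identical(a$probe_id, b$probe_id))
    stop_config("replicate probe sets do not match")
  ok <- !is.na(a$score) & !is.na(b$score) &
    abs(a$score) >= threshold & abs(b$score) >= threshold &
    sign(a$score) == sign(b$score)
  sgn <- ifelse(ok, sign(a$score), 0)
  mean_s <- (a$score + b$score) / 2

  ord <- order(a$tile_id, a$probe_rank)
  calls <- list()
  i <- 1L
  while (i <= length(ord)) {
    j <- i
    while (j < length(ord) &&
           a$tile_id[ord[j + 1L]] == a$tile_id[ord[i]] &&
           a$probe_rank[ord[j + 1L]] == a$probe_rank[ord[j]] + 1L &&
           sgn[ord[j + 1L]] != 0 && sgn[ord[j + 1L]] == sgn[ord[i]]) j <- j + 1L
    run <- ord[i:j]
    if (sgn[ord[i]] != 0 && length(run) >= min_probes) {
      central <- run[ceiling(length(run) / 2)]
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = a$chrom[run[1]],
        start = min(a$start[run]), end = max(a$end[run]),
        direction = if (sgn[ord[i]] > 0) "hypomethylated-in-DC"
                    else "hypomethylated-in-MAC",
        mean_score = mean(mean_s[run]),
        n_probes = length(run),
        replicate_support = "both",
        tile_id = a$tile_id[run[1]],
        central_probe = a$probe_id[central],
        central_mid = as.integer((a$start[central] + a$end[central]) %/% 2),
        stringsAsFactors = FALSE)
    }
    i <- j + 1L
  }
  if (!length(calls))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      mean_score = numeric(0), n_probes = integer(0),
                      replicate_support = character(0),
                      tile_id = character(0), central_probe = character(0),
                      central_mid = integer(0), stringsAsFactors = FALSE)
  else out <- do.call(rbind, calls)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  if (nrow(out)) out$dmr_call_id <- sprintf("call%03d", seq_len(nrow(out)))
  else out$dmr_call_id <- character(0)
  class(out) <- c("DMRCall", "data.frame")
  out
}

#' GC fraction of a sequence string
#' @param s Character scalar over A/C/G/T.
#' @return Fraction of G+C bases.
#' @export
gc_fraction <- function(s) {
  b <- strsplit(s, "")[[1]]
  if (!length(b)) return(NA_real_)
  mean(b %in% c("G", "C"))
}

#' Count CpG dinucleotides in a sequence string
#' @param s Character scalar over A/C/G/T.
#' @return Number of CG occurrences.
#' @export
cpg_count <- function(s) {
  b <- strsplit(s, "")[[1]]
  if (length(b) < 2) return(0L)
  sum(b[-length(b)] == "C" & b[-1] == "G")
}

#' Annotate DMR calls with TSS distance, position class and CpG/GC content
#'
#' The signed distance runs from the central probe midpoint to the
#' nearest TSS, measured in transcription direction (negative =
#' upstream). Position classes: proximal promoter if |distance| <=
#' \code{proximal_bp}; intragenic if the midpoint lies inside a gene body
#' beyond that; intergenic otherwise. CpG count and GC fraction are
#' computed on the window of \code{window_bp} bp centred on the central
#' probe.
#'
#' @param calls A \code{DMRCall} data.frame.
#' @param genome A \code{GenomeModel}.
#' @param proximal_bp Proximal-promoter distance cutoff, bp.
#' @param window_bp Annotation window width, bp.
#' @return The calls with nearest_gene, tss_distance, position_class,
#'   cpg_count and gc_fraction columns.
#' @export
annotate_dmr <- function(calls, genome, proximal_bp = 1000L, window_bp = 500L) {
  g <- genome$genes
  half <- window_bp %/% 2L
  calls$nearest_gene <- NA_character_
  calls$tss_distance <- NA_integer_
  calls$position_class <- NA_character_
  calls$cpg_count <- NA_integer_
  calls$gc_fraction <- NA_real_
  for (i in seq_len(nrow(calls))) {
    mid <- calls$central_mid[i]
    gch <- g[g$chrom == calls$chrom[i], ]
    if (!nrow(gch)) {
      message(sprintf("no TSS on %s; distance undefined for %s",
                      calls$chrom[i], calls$dmr_call_id[i]))
    } else {
      k <- which.min(abs(mid - gch$tss))
      d <- mid - gch$tss[k]
      if (gch$strand[k] == "-") d <- -d
      calls$nearest_gene[i] <- gch$gene_id[k]
      calls$tss_distance[i] <- as.integer(d)
      inside <- any(mid >= gch$start & mid < gch$end)
      calls$position_class[i] <-
        if (abs(d) <= proximal_bp) "proximal_promoter"
        else if (inside) "intragenic"
        else "intergenic"
    }
    s <- genome_window_seq(genome, calls$chrom[i], mid - half, mid + half)
    calls$cpg_count[i] <- cpg_count(s)
    calls$gc_fraction[i] <- gc_fraction(s)
  }
  calls
}

#' Compare DMR calls with the planted registry
#'
#' A planted DMR counts as recovered when a call of the correct chromosome
#' overlaps it; a call not overlapping any planted DMR is a false
#' positive.
#'
#' @param calls A \code{DMRCall} data.frame.
#' @param planted The \code{dmrs} registry of a \code{MethylomeState}.
#' @return List with sensitivity, false-discovery proportion (fdr),
#'   direction correctness among true positives, and the matched tables.
#' @export
evaluate_calls <- function(calls, planted) {
  if (!nrow(planted)) {
    return(list(sensitivity = NA_real_, fdr = if (nrow(calls)) 1 else 0,
                direction_correct = NA_real_, n_called = nrow(calls),
                n_planted = 0L, calls = calls))
  }
  lev <- sort(unique(c(planted$chrom, calls$chrom)))
  pgr <- GenomicRanges::GRanges(factor(planted$chrom, levels = lev),
                                IRanges::IRanges(planted$start + 1L, planted$end))
  if (nrow(calls)) {
    cgr <- GenomicRanges::GRanges(factor(calls$chrom, levels = lev),
                                  IRanges::IRanges(calls$start + 1L, calls$end))
    hits <- GenomicRanges::findOverlaps(cgr, pgr)
    matched_call <- S4Vectors::queryHits(hits)
    matched_dmr <- S4Vectors::subjectHits(hits)
  } else matched_call <- matched_dmr <- integer(0)
  tp_calls <- unique(matched_call)
  sens <- length(unique(matched_dmr)) / nrow(planted)
  fdr <- if (nrow(calls)) (nrow(calls) - length(tp_calls)) / nrow(calls) else 0
  dir_ok <- if (length(matched_call))
    mean(calls$direction[matched_call] == planted$direction[matched_dmr])
  else NA_real_
  list(sensitivity = sens, fdr = fdr, direction_correct = dir_ok,
       n_called = nrow(calls), n_planted = nrow(planted),
       recovered = unique(planted$dmr_id[matched_dmr]))
}

#' Write DMR calls as BED6 plus an extended TSV
#'
#' @param calls An annotated \code{DMRCall} data.frame.
#' @param bed_path,tsv_path Output paths (either may be NULL).
#' @export
write_dmr_calls <- function(calls, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    if (nrow(calls)) {
      gr <- GenomicRanges::GRanges(calls$chrom,
                                   IRanges::IRanges(calls$start + 1L, calls$end))
      gr$name <- paste(calls$dmr_call_id, calls$direction, sep = "|")
      gr$score <- pmin(1000L, as.integer(round(abs(calls$mean_score) * 500)))
      rtracklayer::export(gr, bed_path, format = "BED")
    } else file.create(bed_path)
  }
  if (!is.null(tsv_path)) write_tsv(as.data.frame(calls), tsv_path)
  invisible(NULL)
}
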