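# build a minimal scored MirrorSignal straight from chosen ratios
signal_from_ratios <- function(r_cpg, r_mcpg, replicate = 1L) {
  n <- length(r_cpg)
  data.frame(probe_id = sprintf("p%05d", seq_len(n)), chrom = "chr1",
             start = seq_len(n) * 100L, end = seq_len(n) * 100L + 50L,
             tile_id = "t1", gene_id = "g1", probe_rank = seq_len(n),
             replicate = replicate,
             dc_cpg = 10^r_cpg, mac_cpg = 1,
             dc_mcpg = 10^r_mcpg, mac_mcpg = 1,
             flagged = FALSE, stringsAsFactors = FALSE)
}

test_that("probe design tiles the strand-aware promoter window", {
  cfg <- genome_config(n_chrom = 1L, chrom_len = 40000L, n_genes = 0L,
                       n_cpg_clusters = 0L)
  g <- generate_genome(cfg, seed = 2)
  g$genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                        tss = c(10000L, 30000L), strand = c("+", "-"),
                        start = c(10000L, 25000L), end = c(15000L, 30001L),
                        cpg_class = "low", stringsAsFactors = FALSE)
  probes <- design_probes(g, spacing = 200L, probe_len = 50L)
  plus <- probes[probes$gene_id == "gp", ]
  expect_equal(nrow(plus), 26L)                       # 5000/200 + 1
  expect_equal(range(plus$start), c(6000L, 11000L))   # -4000..+1000
  minus <- probes[probes$gene_id == "gm", ]
  expect_equal(nrow(minus), 26L)
  expect_equal(range(minus$start), c(29000L, 34000L)) # mirrored window
  # determinism
  probes2 <- design_probes(g, spacing = 200L, probe_len = 50L)
  expect_identical(probes, probes2)
})

test_that("median scaling equalizes channels without changing ranks", {
  set.seed(5)
  sig <- signal_from_ratios(rnorm(200), rnorm(200))
  sig$mac_cpg <- sig$dc_cpg * 2           # medians 2:1
  norm <- normalize_channels(sig)
  expect_equal(median(norm$dc_cpg), median(norm$mac_cpg))
  expect_equal(order(norm$dc_cpg), order(sig$dc_cpg))
  # already balanced channels are returned unchanged
  bal <- signal_from_ratios(rep(0, 50), rep(0, 50))
  expect_equal(normalize_channels(bal)$dc_cpg, bal$dc_cpg)
  bad <- bal; bad$dc_cpg <- 0
  expect_error(normalize_channels(bad), "all-zero")
})

test_that("quantile probe filter flags exactly the extreme tails", {
  set.seed(6)
  sig <- signal_from_ratios(rnorm(1000), rnorm(1000))
  none <- filter_probes(sig, 0, 1)
  expect_false(any(none$flagged))
  f <- filter_probes(sig, 0.05, 0.95)
  # oracle: count rows with any channel outside its own empirical quantiles
  expected <- rep(FALSE, 1000)
  for (ch in c("dc_cpg", "mac_cpg", "dc_mcpg", "mac_mcpg")) {
    qs <- quantile(sig[[ch]], c(0.05, 0.95), names = FALSE)
    expected <- expected | sig[[ch]] < qs[1] | sig[[ch]] > qs[2]
  }
  expect_equal(f$flagged, expected)
  # the global maximum of a channel is always flagged at high_q < 1
  sig$dc_cpg[123] <- max(sig$dc_cpg) * 10
  expect_true(filter_probes(sig, 0.001, 0.999)$flagged[123])
})

test_that("mirror statistic reproduces the defining arithmetic", {
  sig <- signal_from_ratios(c(0.5, 0.3), c(-0.5, 0.3))
  s <- mirror_score(sig)
  expect_equal(s$score[1], 1.0)            # reciprocal probe
  expect_equal(s$score[2], 0.0)            # common shift cancels
  # swapping the cell labels negates the score
  swapped <- sig
  swapped[, c("dc_cpg", "mac_cpg")] <- sig[, c("mac_cpg", "dc_cpg")]
  swapped[, c("dc_mcpg", "mac_mcpg")] <- sig[, c("mac_mcpg", "dc_mcpg")]
  expect_equal(mirror_score(swapped)$score[1], -1.0)
  # flagged probes are masked
  sig$flagged[1] <- TRUE
  expect_true(is.na(mirror_score(sig)$score[1]))
})

test_that("mirror statistic is antisymmetric and shift-invariant on random probes", {
  set.seed(7)
  n <- 10000L
  r1 <- rnorm(n); r2 <- rnorm(n)
  sig <- signal_from_ratios(r1, r2)
  s <- mirror_score(sig)$score
  expect_equal(s, r1 - r2, tolerance = 1e-12)
  swapped <- signal_from_ratios(-r1, -r2)
  expect_equal(mirror_score(swapped)$score, -s, tolerance = 1e-12)
  shift <- rnorm(n)
  shifted <- signal_from_ratios(r1 + shift, r2 + shift)
  expect_equal(mirror_score(shifted)$score, s, tolerance = 1e-10)
})

test_that("DMR calling demands replicate-consistent runs", {
  zero <- rbind(signal_from_ratios(rep(0, 20), rep(0, 20), 1L),
                signal_from_ratios(rep(0, 20), rep(0, 20), 2L))
  expect_equal(nrow(call_dmrs(mirror_score(zero))), 0L)

  # strong run in replicate 1 only -> not called
  r <- rep(0, 20); r[5:8] <- 1
  one_rep <- rbind(signal_from_ratios(r, -r, 1L),
                   signal_from_ratios(rep(0, 20), rep(0, 20), 2L))
  expect_equal(nrow(call_dmrs(mirror_score(one_rep))), 0L)

  # present in both -> called once, in the DC direction
  both <- rbind(signal_from_ratios(r, -r, 1L),
                signal_from_ratios(r, -r, 2L))
  calls <- call_dmrs(mirror_score(both))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$direction, "hypomethylated-in-DC")
  expect_equal(calls$n_probes, 4L)
  # label swap flips the direction but not the coordinates
  flipped <- rbind(signal_from_ratios(-r, r, 1L),
                   signal_from_ratios(-r, r, 2L))
  calls2 <- call_dmrs(mirror_score(flipped))
  expect_equal(calls2$direction, "hypomethylated-in-MAC")
  expect_equal(calls2[, c("start", "end")], calls[, c("start", "end")])

  # mismatched probe sets error
  bad <- both[-3, ]
  expect_error(call_dmrs(mirror_score(bad)), "replicate")
})

test_that("planted DMRs are recovered with correct direction end-to-end", {
  run <- std_run()
  expect_gte(run$recovery$sensitivity, 0.9)
  expect_lte(run$recovery$fdr, 0.1)
  expect_equal(run$recovery$direction_correct, 1.0)
})

test_that("annotation classifies TSS distance and window content", {
  cfg <- genome_config(n_chrom = 1L, chrom_len = 40000L, n_genes = 0L,
                       n_cpg_clusters = 0L)
  g <- generate_genome(cfg, seed = 3)
  g$genes <- data.frame(gene_id = "gA", chrom = "chr1", tss = 20000L,
                        strand = "+", start = 20000L, end = 28000L,
                        cpg_class = "low", stringsAsFactors = FALSE)
  mk_call <- function(mid) data.frame(
    chrom = "chr1", start = mid - 100L, end = mid + 100L,
    direction = "hypomethylated-in-DC", mean_score = 1, n_probes = 3L,
    replicate_support = "both", tile_id = "gA", central_probe = "p1",
    central_mid = mid, dmr_call_id = "c1", stringsAsFactors = FALSE)
  ann <- annotate_dmr(mk_call(19500L), g)      # 500 bp upstream
  expect_equal(ann$tss_distance, -500L)
  expect_equal(ann$position_class, "proximal_promoter")
  ann <- annotate_dmr(mk_call(23000L), g)      # 3 kb into the gene body
  expect_equal(ann$tss_distance, 3000L)
  expect_equal(ann$position_class, "intragenic")
  ann <- annotate_dmr(mk_call(5000L), g)       # far upstream, outside gene
  expect_equal(ann$position_class, "intergenic")
})

test_that("CpG counting and GC fraction match a naive string scan", {
  # tandem CG repeats: every dinucleotide counted, GC fraction 1
  s <- strrep("CG", 250)
  expect_equal(cpg_count(s), 250L)
  expect_equal(gc_fraction(s), 1.0)
  g <- std_run()$genome
  set.seed(9)
  for (i in 1:100) {
    ch <- sample(names(g$seqs), 1)
    st <- sample.int(length(g$seqs[[ch]]) - 500L, 1L)
    w <- mirrormeth:::genome_window_seq(g, ch, st, st + 500L)
    b <- strsplit(w, "")[[1]]
    oracle_cpg <- sum(vapply(seq_len(length(b) - 1),
                             function(j) b[j] == "C" && b[j + 1] == "G",
                             logical(1)))
    oracle_gc <- sum(b == "G" | b == "C") / length(b)
    expect_identical(cpg_count(w), as.integer(oracle_cpg))
    expect_equal(gc_fraction(w), oracle_gc)
  }
})

test_that("hybridization intensities scale linearly with pool abundance", {
  fx <- control_fixture()
  fr <- fragment_genome(fx$genome, fx$methylome, coverage = 20, seed = 12)
  pools <- pool_fractions(elute_fragments(fr, seed = 13))
  probes <- data.frame(chrom = "chrC",
                       start = seq(1000L, 28000L, by = 300L))
  probes$end <- probes$start + 50L
  probes$tile_id <- "tile"; probes$gene_id <- NA_character_
  probes$probe_rank <- seq_len(nrow(probes))
  probes$probe_id <- sprintf("p%04d", probes$probe_rank)
  sig1 <- simulate_hybridization(pools, pools, probes,
                                 hyb_params(sdlog = 0), seed = 14)
  # same pools on both channels, no noise -> ratio is pure dye bias
  expect_equal(sig1$dc_cpg / sig1$mac_cpg,
               rep(hyb_params()$dye_bias, nrow(probes)))
  # doubled abundance doubles above-background intensity
  doubled <- rbind(pools, pools)
  sig2 <- simulate_hybridization(doubled, doubled, probes,
                                 hyb_params(sdlog = 0, background = 0),
                                 seed = 14)
  base <- simulate_hybridization(pools, pools, probes,
                                 hyb_params(sdlog = 0, background = 0),
                                 seed = 14)
  nz <- base$mac_cpg > 0
  expect_equal(sig2$mac_cpg[nz] / base$mac_cpg[nz],
               rep(2, sum(nz)))
  # determinism
  expect_identical(base, simulate_hybridization(pools, pools, probes,
                                                hyb_params(sdlog = 0,
                                                           background = 0),
                                                seed = 14))
})
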