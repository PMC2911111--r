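test_that("bisulfite conversion follows the CpG-context rule", {
  expect_equal(bisulfite_convert("ACGTCC", c(TRUE)), "ACGTTT")
  expect_equal(bisulfite_convert("ACGTCC", c(FALSE)), "ATGTTT")
  expect_equal(bisulfite_convert("AGTTAG"), "AGTTAG")   # no C: unchanged
  expect_error(bisulfite_convert("ACGT", logical(0)), "CpG cytosines")
})

test_that("converted sequences contain C only at methylated CpGs", {
  set.seed(41)
  for (i in 1:25) {
    s <- random_dna(200)
    b <- strsplit(s, "")[[1]]
    n_cpg <- sum(b[-length(b)] == "C" & b[-1] == "G")
    flags <- sample(c(TRUE, FALSE), n_cpg, replace = TRUE)
    conv <- bisulfite_convert(s, flags)
    cb <- strsplit(conv, "")[[1]]
    c_pos <- which(cb == "C")
    meth_pos <- which(b[-length(b)] == "C" & b[-1] == "G")[flags]
    expect_identical(c_pos, as.integer(meth_pos))
  }
})

test_that("T-cleavage cuts 3' of every U and conserves the transcript", {
  expect_equal(mirrormeth:::split_after_u("GAUCGU"), c("GAU", "CGU"))
  expect_equal(mirrormeth:::split_after_u("GGCAGC"), "GGCAGC")  # no U
  set.seed(42)
  for (i in 1:20) {
    tr <- paste(sample(c("A", "C", "G", "U"), 120, TRUE), collapse = "")
    parts <- mirrormeth:::split_after_u(tr)
    expect_identical(paste(parts, collapse = ""), tr)
    # every part except possibly the last ends in U and has no internal U
    expect_true(all(grepl("^[^U]*U?$", parts)))
  }
})

test_that("a methylated CpG reads G where an unmethylated one reads A", {
  s <- "ATCGAATTGG"  # single CpG at position 3
  conv_m <- bisulfite_convert(s, TRUE)
  conv_u <- bisulfite_convert(s, FALSE)
  tr_m <- mirrormeth:::to_rna(mirrormeth:::revcomp(conv_m))
  tr_u <- mirrormeth:::to_rna(mirrormeth:::revcomp(conv_u))
  d <- which(strsplit(tr_m, "")[[1]] != strsplit(tr_u, "")[[1]])
  expect_length(d, 1L)
  expect_equal(substr(tr_m, d, d), "G")
  expect_equal(substr(tr_u, d, d), "A")
})

test_that("fragment masses equal the residue-sum oracle with +16 Da per methyl-CpG", {
  frag <- list(fragment_id = 1L, sequence = "GAU", span = c(1L, 3L),
               cpg_members = integer(0), n_cpg = 0L,
               masses = NA)
  frag$masses <- sum(RNA_RESIDUE_MASS[c("G", "A", "U")]) + RNA_TERMINAL_MASS
  class(frag) <- "CleavageFragment"
  oracle <- RNA_RESIDUE_MASS[["G"]] + RNA_RESIDUE_MASS[["A"]] +
    RNA_RESIDUE_MASS[["U"]] + RNA_TERMINAL_MASS
  expect_equal(fragment_mass(frag, 0), oracle, tolerance = 1e-12)
  expect_identical(fragment_mass(frag, 0), fragment_mass(frag, 0))

  g <- std_run()$genome
  set.seed(43)
  for (i in 1:40) {
    ch <- sample(names(g$seqs), 1)
    st <- sample.int(length(g$seqs[[ch]]) - 260L, 1L)
    amp <- design_amplicon(g, ch, st, st + 250L)
    frags <- cleave_transcript(amp)
    for (fr in frags) {
      res <- strsplit(fr$sequence, "")[[1]]
      base_oracle <- sum(RNA_RESIDUE_MASS[res]) + RNA_TERMINAL_MASS
      for (k in 0:fr$n_cpg)
        expect_equal(fragment_mass(fr, k), base_oracle + 16.00 * k,
                     tolerance = 1e-9)
    }
    # every amplicon CpG maps into exactly one fragment
    members <- unlist(lapply(frags, `[[`, "cpg_members"))
    expect_identical(sort(members), seq_along(amp$cpg_pos))
    # concatenated fragments rebuild the transcript; total mass additivity
    tr <- paste(vapply(frags, `[[`, "", "sequence"), collapse = "")
    expect_equal(nchar(tr), amp$end - amp$start)
    total <- sum(vapply(frags, function(f) f$masses[1] - RNA_TERMINAL_MASS,
                        numeric(1)))
    expect_equal(total, sum(RNA_RESIDUE_MASS[strsplit(tr, "")[[1]]]),
                 tolerance = 1e-9)
  }
  expect_error(cleave_transcript(design_amplicon(g, "chr1", 100, 400), "C"),
               "unsupported")
})

test_that("unit quantification evaluates the intensity-weighted formula", {
  unit1 <- list(fragment_id = 1L, sequence = "CCGGGAU", span = c(1L, 7L),
                cpg_members = 1L, n_cpg = 1L,
                masses = c(3000, 3016))
  unit2 <- list(fragment_id = 2L, sequence = "GGCCGGAU", span = c(8L, 15L),
                cpg_members = 2:3, n_cpg = 2L,
                masses = c(4000, 4016, 4032))
  frags <- list(unit1, unit2)
  # noiseless 60% methylation on the 1-CpG unit
  m <- quantify_units(frags, list(c(0.4, 0.6), c(1, 2, 1)))
  expect_equal(m$ratio[m$fragment_id == 1], 0.6, tolerance = 1e-6)
  # the 2-CpG worked example: (0*1 + 1*2 + 2*1) / (2 * 4)
  expect_equal(m$ratio[m$fragment_id == 2], 0.5, tolerance = 1e-12)
  # all intensity at k = 0
  m0 <- quantify_units(frags, list(c(1, 0), c(1, 0, 0)))
  expect_equal(m0$ratio, c(0, 0))
  # all-zero intensities: flagged unmeasurable, no ratio
  mz <- quantify_units(frags, list(c(0, 0), c(1, 2, 1)))
  expect_false(mz$measurable[1])
  expect_true(is.na(mz$ratio[1]))
})

test_that("out-of-window and colliding peaks are flagged, never quantified", {
  lo <- list(fragment_id = 1L, sequence = "CG", span = c(1L, 2L),
             cpg_members = 1L, n_cpg = 1L, masses = c(600, 616))
  ok <- list(fragment_id = 2L, sequence = "X", span = c(3L, 8L),
             cpg_members = 2L, n_cpg = 1L, masses = c(2000, 2016))
  clash <- list(fragment_id = 3L, sequence = "Y", span = c(9L, 14L),
                cpg_members = 3L, n_cpg = 1L, masses = c(2016.2, 2032.2))
  m <- quantify_units(list(lo, ok, clash),
                      list(c(1, 1), c(1, 1), c(1, 1)))
  expect_false(m$measurable[m$fragment_id == 1])   # below 1,500 Da
  expect_false(m$measurable[m$fragment_id == 2])   # collides with 3
  expect_false(m$measurable[m$fragment_id == 3])
  expect_true(all(is.na(m$ratio)))
  # widen the resolution criterion: no collision at 0.1 Da
  m2 <- quantify_units(list(ok, clash), list(c(1, 1), c(1, 1)),
                       mass_resolution = 0.1)
  expect_true(all(m2$measurable))
})

test_that("noiseless quantification recovers population fractions; noisy error is small", {
  set.seed(44)
  n_units <- 1000L
  errs0 <- errs <- numeric(n_units)
  for (i in seq_len(n_units)) {
    n_cpg <- sample(1:3, 1)
    p <- runif(n_cpg)
    frag <- list(fragment_id = 1L, sequence = "Z", span = c(1L, 2L),
                 cpg_members = seq_len(n_cpg), n_cpg = n_cpg,
                 masses = 3000 + 0:n_cpg * 16)
    pmf <- mirrormeth:::pois_binom_pmf(p)
    m0 <- quantify_units(list(frag), list(pmf))
    errs0[i] <- abs(m0$ratio - mean(p))
    noisy <- pmf * rlnorm(length(pmf), -0.1^2 / 2, 0.1)
    m1 <- quantify_units(list(frag), list(noisy))
    errs[i] <- abs(m1$ratio - mean(p))
  }
  expect_lt(max(errs0), 1e-6)
  expect_lte(mean(errs), 0.05)
})

test_that("concordance statistic reproduces the counting rule", {
  mk <- function(n, n_disc) {
    calls <- data.frame(region_id = sprintf("r%02d", 1:n),
                        direction = "hypomethylated-in-DC",
                        stringsAsFactors = FALSE)
    ms <- data.frame(region_id = calls$region_id,
                     mean_dc = 0.1, mean_mac = 0.9)
    if (n_disc > 0) {   # discordant: MS says DC more methylated
      ms$mean_dc[seq_len(n_disc)] <- 0.9
      ms$mean_mac[seq_len(n_disc)] <- 0.1
    }
    list(calls = calls, ms = ms)
  }
  toy <- mk(25, 3)
  res <- assess_concordance(toy$calls, toy$ms)
  expect_equal(res$n_regions, 25L)
  expect_equal(res$n_concordant, 22L)
  expect_equal(res$pct_concordant, 88.0)
  all_ok <- mk(10, 0)
  expect_equal(assess_concordance(all_ok$calls, all_ok$ms)$pct_concordant, 100)
  # control regions agree when |difference| < delta_min
  ctrl <- data.frame(region_id = c("c1", "c2"), direction = "none")
  ms <- data.frame(region_id = c("c1", "c2"),
                   mean_dc = c(0.50, 0.2), mean_mac = c(0.55, 0.8))
  res <- assess_concordance(ctrl, ms, delta_min = 0.1)
  expect_equal(res$n_concordant, 1L)
  expect_error(assess_concordance(ctrl,
                                  data.frame(region_id = "zz", mean_dc = 1,
                                             mean_mac = 1)),
               "no regions shared")
})

test_that("end-to-end assay concordance is high on default synthetic data", {
  run <- std_run()
  expect_false(is.null(run$concordance))
  expect_gte(run$concordance$pct_concordant, 90)
})

test_that("amplicon design enforces length bounds and tagged primers", {
  g <- std_run()$genome
  amp <- design_amplicon(g, "chr1", 1000, 1400)
  expect_equal(nchar(amp$sequence), 400L)
  expect_equal(substr(amp$fwd_primer, 1, 10), "AGGAAGAGAG")
  expect_true(startsWith(amp$rev_primer, "CAGTAATACGACTCACTATAGGG"))
  expect_error(design_amplicon(g, "chr1", 1000, 1100), "outside bounds")
  expect_error(design_amplicon(g, "chr1", 1000, 2000), "outside bounds")
})
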