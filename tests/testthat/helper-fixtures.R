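# shared fixtures, built once per test session

.fixture_cache <- new.env(parent = emptyenv())

# default end-to-end run shared by the recovery and concordance tests
std_run <- function() {
  if (is.null(.fixture_cache$run))
    .fixture_cache$run <- run_pipeline(default_config(seed = 1))
  .fixture_cache$run
}

small_genome <- function(seed = 11) {
  key <- paste0("genome", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_genome(
      genome_config(n_chrom = 1L, chrom_len = 60000L, n_genes = 6L,
                    n_cpg_clusters = 8L), seed = seed)
  .fixture_cache[[key]]
}

# hand-built genome with a CpG-free segment, an imprinted-like segment
# (dense CpGs at 50% methylation) and a fully methylated dense segment;
# used to exercise the fractionation controls
control_fixture <- function() {
  if (!is.null(.fixture_cache$control)) return(.fixture_cache$control)
  len <- 30000L
  base <- rep(c("A", "T", "G", "A", "C", "T"), length.out = len)  # no CG
  plant <- function(s, from, to, every) {
    pos <- seq(from, to, by = every)
    s[pos] <- "C"; s[pos + 1L] <- "G"
    s
  }
  base <- plant(base, 10001L, 11999L, 50L)   # SNRPN-like, density 0.02
  base <- plant(base, 20001L, 21999L, 20L)   # dense, density 0.05
  seqs <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(seqs) <- "chrC"
  genome <- structure(list(
    seqs = seqs,
    genes = data.frame(gene_id = character(0), chrom = character(0),
                       tss = integer(0), strand = character(0),
                       start = integer(0), end = integer(0),
                       cpg_class = character(0), stringsAsFactors = FALSE),
    cpg_clusters = data.frame(),
    config = genome_config(n_chrom = 1L, chrom_len = len, n_genes = 0L,
                           n_cpg_clusters = 0L)),
    class = "GenomeModel")
  sites <- cpg_sites(genome)
  sites$initial <- ifelse(sites$pos < 15000L, 0.5, 1.0)
  sites$final <- sites$initial
  sites$onset <- NA_real_
  sites$steepness <- 0.3
  sites$is_dmr <- FALSE
  sites$dmr_id <- NA_character_
  sites$mac_offset <- 0
  sites$dc_offset <- 0
  methylome <- structure(list(sites = sites,
                              dmrs = data.frame(),
                              config = methylome_config()),
                         class = "MethylomeState")
  regions <- data.frame(
    region_id = c("Empty", "SNRPN_like", "Dense_methylated"),
    chrom = "chrC",
    start = c(1000L, 10000L, 20000L),
    end = c(5000L, 12000L, 22000L),
    stringsAsFactors = FALSE)
  .fixture_cache$control <- list(genome = genome, methylome = methylome,
                                 regions = regions)
  .fixture_cache$control
}

# random DNA string (possibly containing CpGs)
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

expect_fraction <- function(x) {
  expect_true(all(x >= 0 & x <= 1))
}
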