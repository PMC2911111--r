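#' Default end-to-end pipeline configuration
#'
#' The defaults define the standard simulated study: a 2 x 100-kb
#' genome with 20 genes, 10 planted DMRs, fragment coverage 30x, two
#' biological replicates of the dual reciprocal hybridizations, score
#' threshold 0.6 over >= 2 consecutive probes, EpiTYPER validation of
#' every called DMR plus unplanted control regions, and the downstream
#' kinetics / association / ChIP reports.
#'
#' @param seed Master seed; every stochastic stage derives its own
#'   stream from it.
#' @return Nested list of class \code{mirrormeth_config}.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    genome = genome_config(),
    methylome = list(n_dmrs = 10L,
                     dmr_position_mix = c(proximal = 0.4, intragenic = 0.3,
                                          intergenic = 0.3),
                     config = methylome_config()),
    mcip = list(coverage = 30, mean_len = 375, sd_len = 50,
                affinity = affinity_params()),
    array = list(spacing = 200L, probe_len = 50L, threshold = 0.6,
                 min_probes = 2L, low_q = 0.001, high_q = 0.999,
                 n_replicates = 2L, hyb = hyb_params()),
    epityper = list(noise_sd = 0.1, delta_min = 0.1,
                    n_control_regions = 6L, amplicon_len = 400L),
    report = list(times = c(0, 6, 18, 30, 42, 51, 66, 168),
                  min_delta = 0.2, fc_threshold = 2),
    comparison_time_h = 168
  ), class = "mirrormeth_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The file must contain an explicit \code{seed} field.
#' @param path File path.
#' @param config A configuration list.
#' @return The configuration (reader) or the path (writer), invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop_config("config file must set an explicit seed")
  cfg <- default_config(seed = raw$seed)
  utils::modifyList(cfg, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# regions assayed by mass spectrometry: every called DMR plus
# array-negative control regions sampled from unplanted promoter space
epityper_regions <- function(calls, genome, methylome, n_controls,
                             amp_len, seed) {
  set.seed(seed)
  half <- amp_len %/% 2L
  regions <- data.frame(region_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        direction = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(calls))) {
    mid <- calls$central_mid[i]
    regions <- rbind(regions, data.frame(
      region_id = calls$dmr_call_id[i], chrom = calls$chrom[i],
      start = as.integer(mid - half), end = as.integer(mid + half),
      direction = calls$direction[i], stringsAsFactors = FALSE))
  }
  g <- genome$genes
  planted <- methylome$dmrs
  tries <- 0L
  while (sum(regions$direction == "none") < n_controls && tries < 500L) {
    tries <- tries + 1L
    row <- g[sample.int(nrow(g), 1L), ]
    off <- sample(seq(-2000L, 500L), 1L)
    mid <- row$tss + (if (row$strand == "+") off else -off)
    st <- mid - half; en <- mid + half
    if (st < 0 || en > length(genome$seqs[[row$chrom]])) next
    near_dmr <- nrow(planted) &&
      any(planted$chrom == row$chrom & st < planted$end + 1000L &
          en > planted$start - 1000L)
    if (near_dmr) next
    n_cpg <- sum(methylome$sites$chrom == row$chrom &
                 methylome$sites$pos >= st & methylome$sites$pos < en)
    if (n_cpg < 2L) next
    regions <- rbind(regions, data.frame(
      region_id = sprintf("ctrl%02d", sum(regions$direction == "none") + 1L),
      chrom = row$chrom, start = as.integer(st), end = as.integer(en),
      direction = "none", stringsAsFactors = FALSE))
  }
  regions
}

#' Mean measurable-unit methylation ratio per region and state
#'
#' Regions with no measurable unit in one of the states are dropped:
#' they are "not detected" by the mass-spec assay.
#'
#' @param units Output of [simulate_epityper()].
#' @return data.frame with region_id, mean_dc, mean_mac.
#' @export
ms_region_means <- function(units) {
  ok <- units[units$measurable & !is.na(units$ratio), ]
  if (!nrow(ok)) return(data.frame(region_id = character(0),
                                   mean_dc = numeric(0),
                                   mean_mac = numeric(0)))
  agg <- stats::aggregate(ratio ~ region_id + state, ok, mean)
  wide <- stats::reshape(agg, idvar = "region_id", timevar = "state",
                         direction = "wide")
  names(wide) <- sub("^ratio\\.", "mean_", tolower(names(wide)))
  wide[stats::complete.cases(wide), , drop = FALSE]
}

#' Run the full simulated discovery-and-validation pipeline
#'
#' Executes, from one master seed: genome and methylome synthesis, MCIp
#' fractionation of the DC and MAC day-7 genomes for two biological
#' replicates, the dual reciprocal hybridizations, probe filtering and
#' mirror scoring, replicate-consistent DMR calling and annotation,
#' EpiTYPER-style validation with concordance assessment, kinetics
#' classification of DMR CpGs, and the expression-association report.
#' With \code{out_dir} set, all interface files (FASTA, BED, TSV, config,
#' summary) are written.
#'
#' @param config A [default_config()]-shaped list.
#' @param out_dir Optional output directory.
#' @return List with all stage outputs and a \code{summary} list
#'   (planted vs called DMRs, sensitivity, FDR, direction correctness,
#'   concordance, kinetics class table, association P-values).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  genome <- stage("synthetic_data", generate_genome(config$genome,
                                                    seed = child_seed(seed, 1L)))
  methylome <- stage("synthetic_data", plant_methylome(
    genome, n_dmrs = config$methylome$n_dmrs,
    dmr_position_mix = config$methylome$dmr_position_mix,
    seed = child_seed(seed, 2L), config = config$methylome$config))

  # the custom array tiles promoters plus a few larger genomic
  # intervals; planted non-promoter DMR neighbourhoods stand in for the
  # latter so the array has a chance to interrogate them
  extra <- NULL
  if (nrow(methylome$dmrs)) {
    extra <- data.frame(chrom = methylome$dmrs$chrom,
                        start = pmax(methylome$dmrs$start - 2000L, 0L),
                        end = methylome$dmrs$end + 2000L,
                        region_id = paste0("tile_", methylome$dmrs$dmr_id),
                        stringsAsFactors = FALSE)
  }
  probes <- stage("array_pipeline", design_probes(
    genome, spacing = config$array$spacing,
    probe_len = config$array$probe_len, extra_regions = extra))

  tcomp <- config$comparison_time_h
  signals <- list()
  pools_by_rep <- list()
  for (rep in seq_len(config$array$n_replicates)) {
    pools <- list()
    for (st in c("DC", "MAC")) {
      fr <- stage("mcip_sim", fragment_genome(
        genome, methylome, state = st, time_h = tcomp,
        mean_len = config$mcip$mean_len, sd_len = config$mcip$sd_len,
        coverage = config$mcip$coverage,
        seed = child_seed(seed, 10L * rep + match(st, c("DC", "MAC")))))
      prof <- stage("mcip_sim", elute_fragments(
        fr, config$mcip$affinity,
        seed = child_seed(seed, 20L * rep + match(st, c("DC", "MAC")))))
      pools[[st]] <- stage("mcip_sim", pool_fractions(prof))
    }
    pools_by_rep[[rep]] <- pools
    signals[[rep]] <- stage("array_pipeline", simulate_hybridization(
      pools$DC, pools$MAC, probes, config$array$hyb,
      seed = child_seed(seed, 30L + rep), replicate = rep))
  }
  signal <- do.call(rbind, signals)
  signal <- stage("array_pipeline", normalize_channels(signal))
  signal <- stage("array_pipeline", filter_probes(
    signal, config$array$low_q, config$array$high_q))
  signal <- stage("array_pipeline", mirror_score(signal))
  calls <- stage("array_pipeline", call_dmrs(
    signal, threshold = config$array$threshold,
    min_probes = config$array$min_probes))
  calls <- stage("array_pipeline", annotate_dmr(calls, genome))
  recovery <- evaluate_calls(calls, methylome$dmrs)

  # EpiTYPER validation of calls plus array-negative controls
  regions <- stage("epityper_sim", epityper_regions(
    calls, genome, methylome, config$epityper$n_control_regions,
    config$epityper$amplicon_len, seed = child_seed(seed, 40L)))
  concordance <- NULL
  units <- NULL
  if (nrow(regions)) {
    units <- stage("epityper_sim", simulate_epityper(
      genome, methylome, regions, states = c("DC", "MAC"),
      time_h = tcomp, noise_sd = config$epityper$noise_sd,
      seed = child_seed(seed, 41L)))
    means <- ms_region_means(units)
    if (nrow(means)) {
      concordance <- stage("epityper_sim", assess_concordance(
        regions[, c("region_id", "direction")], means,
        delta_min = config$epityper$delta_min))
    }
  }

  # kinetics of DMR CpGs against flat controls
  dmr_sites <- methylome$sites[methylome$sites$is_dmr, ]
  flat_idx <- which(!methylome$sites$is_dmr)
  set.seed(child_seed(seed, 50L))
  flat_pick <- sample(flat_idx, min(length(flat_idx), nrow(dmr_sites)))
  sub <- methylome
  sub$sites <- rbind(dmr_sites, methylome$sites[flat_pick, ])
  tc <- sample_timecourse(sub, times = config$report$times, states = "DC")
  kinetics <- stage("analysis_report", classify_kinetics(
    tc, min_delta = config$report$min_delta,
    steepness = config$methylome$config$steepness))
  kinetics <- merge(kinetics,
                    sub$sites[, c("chrom", "pos", "is_dmr", "dmr_id")],
                    by = c("chrom", "pos"))

  # expression association over DMR-annotated genes
  association <- NULL
  expr <- NULL
  dmr_genes <- unique(calls$nearest_gene[!is.na(calls$nearest_gene)])
  if (length(dmr_genes) >= 4) {
    expr <- stage("analysis_report", simulate_expression(
      genome$genes$gene_id, dmr_genes, seed = child_seed(seed, 60L)))
    norm <- normalize_expression(expr$mat,
                                 which(expr$samples$state == "MO"))
    ann <- calls[!is.na(calls$nearest_gene),
                 c("nearest_gene", "cpg_count", "gc_fraction")]
    names(ann)[1] <- "gene_id"
    ann <- ann[!duplicated(ann$gene_id), ]
    association <- stage("analysis_report", expression_association(
      ann, norm, expr$samples, fc_threshold = config$report$fc_threshold))
  }

  summary <- list(
    n_planted = nrow(methylome$dmrs),
    n_called = nrow(calls),
    sensitivity = recovery$sensitivity,
    fdr = recovery$fdr,
    direction_correct = recovery$direction_correct,
    pct_concordant = if (!is.null(concordance)) concordance$pct_concordant
                     else NA_real_,
    n_ms_regions = if (!is.null(concordance)) concordance$n_regions
                   else 0L,
    kinetics_class_table = table(planted = ifelse(kinetics$is_dmr,
      "dmr", "flat"), called = kinetics$class),
    cpg_p_value = if (!is.null(association) &&
                      !is.null(association$cpg_test))
      association$cpg_test$p_value else NA_real_,
    gc_p_value = if (!is.null(association) &&
                     !is.null(association$gc_test))
      association$gc_test$p_value else NA_real_)

  result <- list(genome = genome, methylome = methylome, probes = probes,
                 signal = signal, calls = calls, recovery = recovery,
                 regions = regions, units = units,
                 concordance = concordance, kinetics = kinetics,
                 expression = expr, association = association,
                 summary = summary, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# write every interface file of a pipeline run
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_genome_fasta(result$genome, p("genome.fa"))
  write_tss_bed(result$genome, p("tss.bed"))
  write_dmr_bed(result$methylome$dmrs, p("planted_dmrs.bed"))
  write_methylation_tsv(
    sample_timecourse(result$methylome,
                      times = result$config$report$times),
    p("methylation_timecourse.tsv"))
  write_tsv(as.data.frame(result$probes), p("probes.tsv"))
  write_tsv(as.data.frame(result$signal), p("probe_signals.tsv"))
  write_dmr_calls(result$calls, p("dmr_calls.bed"), p("dmr_calls.tsv"))
  if (!is.null(result$units)) write_tsv(result$units, p("epityper_units.tsv"))
  write_tsv(result$kinetics, p("kinetics.tsv"))
  write_config(result$config, p("config.yaml"))
  s <- result$summary
  txt <- c(
    sprintf("planted DMRs:          %d", s$n_planted),
    sprintf("called DMRs:           %d", s$n_called),
    sprintf("sensitivity:           %.3f", s$sensitivity),
    sprintf("false-discovery prop.: %.3f", s$fdr),
    sprintf("direction correct:     %.3f", s$direction_correct),
    sprintf("assay concordance:     %.1f%% (%d regions)",
            s$pct_concordant, s$n_ms_regions),
    sprintf("CpG-content MWU P:     %.3f", s$cpg_p_value),
    sprintf("GC-content MWU P:      %.3f", s$gc_p_value))
  writeLines(txt, p("summary.txt"))
  sdf <- data.frame(metric = c("n_planted", "n_called", "sensitivity",
                               "fdr", "direction_correct",
                               "pct_concordant", "cpg_p_value",
                               "gc_p_value"),
                    value = c(s$n_planted, s$n_called, s$sensitivity,
                              s$fdr, s$direction_correct,
                              s$pct_concordant, s$cpg_p_value,
                              s$gc_p_value))
  write_tsv(sdf, p("summary.tsv"))
  invisible(out_dir)
}
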