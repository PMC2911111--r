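#' Fit demethylation kinetics for one CpG
#'
#' Least-squares fit of the anchored logistic decay
#' ([demethylation_curve()]) to a sampled DC-lineage time course, and
#' classification of the estimated onset: early for onsets up to 46.5 h,
#' late beyond (46.5 h is the midpoint of the unassigned (42, 51] h gap
#' between the two observed kinetics classes); "none" when the fitted
#' total change is below \code{min_delta} or the profile rises beyond
#' noise (demethylation is monotone; a gaining profile is flagged).
#'
#' @param times Hours, at least 4 points including 0.
#' @param fractions Observed methylation fractions at \code{times}.
#' @param min_delta Minimum initial-to-final change to call an event.
#' @param steepness Fixed logistic slope used in the fit (per hour).
#' @param early_cut Onset boundary between early and late classes, h.
#' @param rise_tol Maximum tolerated upward step before the profile is
#'   flagged non-monotone.
#' @return List of class \code{KineticsFit}: onset_h, initial, final,
#'   delta, class, flagged_nonmonotone, sse.
#' @export
fit_demethylation_kinetics <- function(times, fractions, min_delta = 0.2,
                                       steepness = 0.3, early_cut = 46.5,
                                       rise_tol = 0.15) {
  stopifnot(length(times) >= 4, 0 %in% times,
            length(times) == length(fractions))
  o <- order(times)
  t <- times[o]; y <- fractions[o]
  rises <- diff(y)
  flagged <- any(rises > rise_tol)
  init0 <- y[1]; fin0 <- min(y)
  if (flagged || (init0 - fin0) < min_delta / 2) {
    return(structure(list(onset_h = NA_real_, initial = init0,
                          final = fin0, delta = init0 - fin0,
                          class = "none", flagged_nonmonotone = flagged,
                          sse = NA_real_), class = "KineticsFit"))
  }
  mid <- (init0 + fin0) / 2
  below <- which(y <= mid)
  onset0 <- if (length(below)) {
    i <- below[1]
    if (i == 1) t[1] else {
      t[i - 1] + (t[i] - t[i - 1]) * (y[i - 1] - mid) /
        max(y[i - 1] - y[i], 1e-9)
    }
  } else max(t)
  obj <- function(par) {
    f <- demethylation_curve(t, par[1], par[2], par[3], steepness)
    sum((y - f)^2)
  }
  fit <- optim(c(init0, fin0, onset0), obj, method = "L-BFGS-B",
               lower = c(0, 0, 1), upper = c(1, 1, max(t) + 48))
  est <- fit$par
  delta <- est[1] - est[2]
  cls <- if (delta < min_delta) "none"
         else if (est[3] <= early_cut) "early" else "late"
  structure(list(onset_h = if (cls == "none") NA_real_ else est[3],
                 initial = est[1], final = est[2], delta = delta,
                 class = cls, flagged_nonmonotone = FALSE, sse = fit$value),
            class = "KineticsFit")
}

#' Classify demethylation kinetics for a sampled time course table
#'
#' @param timecourse Long table (chrom, pos, state, time_h, fraction) as
#'   produced by [sample_timecourse()]; only DC rows are used.
#' @param ... Passed to [fit_demethylation_kinetics()].
#' @return data.frame with one row per CpG: chrom, pos, onset_h,
#'   initial, final, delta, class.
#' @export
classify_kinetics <- function(timecourse, ...) {
  dc <- timecourse[timecourse$state == "DC", ]
  key <- paste(dc$chrom, dc$pos)
  out <- lapply(split(dc, key), function(d) {
    f <- fit_demethylation_kinetics(d$time_h, d$fraction, ...)
    data.frame(chrom = d$chrom[1], pos = d$pos[1], onset_h = f$onset_h,
               initial = f$initial, final = f$final, delta = f$delta,
               class = f$class, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos), ]
  rownames(res) <- NULL
  res
}

#' Mann-Whitney U test with exact enumeration for small groups
#'
#' U counts the pairs (x_i, y_j) with x_i > y_j (ties count 1/2),
#' computed by the mid-rank formula. For group sizes of at most
#' \code{exact_max} each, the two-sided P-value is obtained by exact
#' enumeration of all choose(n1 + n2, n1) group assignments of the
#' observed values (so ties are handled exactly); larger groups use the
#' normal approximation with tie correction.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest group size for which enumeration is used.
#' @return List with U, p_value, method and the group sizes.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0)
    stop_config("both groups must be non-empty for the Mann-Whitney test")
  u_stat <- function(xi, yi) {
    r <- rank(c(xi, yi))
    sum(r[seq_along(xi)]) - length(xi) * (length(xi) + 1) / 2
  }
  U <- u_stat(x, y)
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    comb <- c(x, y)
    idx <- combn(n1 + n2, n1)
    us <- apply(idx, 2, function(i) u_stat(comb[i], comb[-i]))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    ties <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation with tie correction"
  }
  list(U = U, p_value = p, method = method, n1 = n1, n2 = n2)
}

#' Normalize an expression matrix to the 75th percentile and monocyte
#' baseline
#'
#' Each sample (column) is scaled so its 75th percentile equals
#' \code{target}; each gene (row) is then divided by the median of the
#' monocyte samples, so the monocyte baseline is 1.
#'
#' @param mat Gene x sample matrix of positive expression values.
#' @param mo_cols Column indices (or names) of the monocyte samples.
#' @param target Common 75th-percentile value after scaling.
#' @return The normalized matrix.
#' @export
normalize_expression <- function(mat, mo_cols, target = 100) {
  q75 <- apply(mat, 2, quantile, probs = 0.75, names = FALSE)
  if (any(q75 <= 0)) stop_config("non-positive 75th percentile in a sample")
  mat <- sweep(mat, 2, target / q75, `*`)
  base <- apply(mat[, mo_cols, drop = FALSE], 1, median)
  base[base <= 0] <- min(base[base > 0], 1)
  sweep(mat, 1, base, `/`)
}

#' Simulate a DC differentiation expression time course
#'
#' Generates a positive expression matrix for the given genes over
#' monocyte baseline samples and DC time-course samples. About half of
#' the DMR-associated genes are induced (fold change sampled from
#' \code{up_fold_range} reached with a delay), the rest and all other
#' genes stay flat up to lognormal noise — mirroring the observation
#' that demethylation is not universally followed by induction.
#'
#' @param gene_ids Character vector of gene ids.
#' @param dmr_gene_ids Genes associated with a DMR.
#' @param p_up Probability a DMR gene is up-regulated.
#' @param times DC sampling times, h.
#' @param n_mo_donors Number of monocyte baseline samples.
#' @param up_fold_range Fold-change range of induced genes.
#' @param noise_sdlog Lognormal expression noise.
#' @param seed Integer seed.
#' @return List with the raw matrix \code{mat}, sample annotation
#'   \code{samples}, and the set of truly induced genes \code{up_genes}.
#' @export
simulate_expression <- function(gene_ids, dmr_gene_ids, p_up = 0.5,
                                times = c(6, 18, 30, 42, 51, 66, 168),
                                n_mo_donors = 3L,
                                up_fold_range = c(3, 10),
                                noise_sdlog = 0.15, seed = 1L) {
  set.seed(seed)
  up_genes <- dmr_gene_ids[runif(length(dmr_gene_ids)) < p_up]
  samples <- data.frame(
    sample = c(sprintf("MO_d%d", seq_len(n_mo_donors)),
               sprintf("DC_%dh", times)),
    state = c(rep("MO", n_mo_donors), rep("DC", length(times))),
    time_h = c(rep(0, n_mo_donors), times),
    stringsAsFactors = FALSE)
  basal <- rlnorm(length(gene_ids), meanlog = log(50), sdlog = 1)
  mat <- matrix(0, length(gene_ids), nrow(samples),
                dimnames = list(gene_ids, samples$sample))
  fold <- setNames(rep(1, length(gene_ids)), gene_ids)
  fold[up_genes] <- runif(length(up_genes), up_fold_range[1], up_fold_range[2])
  onset <- setNames(runif(length(gene_ids), 24, 60), gene_ids)
  for (j in seq_len(nrow(samples))) {
    t <- samples$time_h[j]
    induction <- 1 + (fold - 1) / (1 + exp(-0.2 * (t - onset)))
    mu <- basal * if (samples$state[j] == "DC") induction else 1
    mat[, j] <- mu * rlnorm(length(gene_ids), -noise_sdlog^2 / 2, noise_sdlog)
  }
  list(mat = mat, samples = samples, up_genes = up_genes)
}

#' Association of expression change with local CpG/GC content at DMRs
#'
#' Splits DMR-associated genes into up-regulated (maximum DC fold change
#' over the monocyte baseline at any time >= \code{fc_threshold}) and
#' unchanged, then compares the CpG counts — and separately the GC
#' fractions — of the two groups' DMR annotation windows with the
#' two-sided Mann-Whitney U test ([mann_whitney_u()]).
#'
#' @param dmr_genes data.frame with gene_id, cpg_count, gc_fraction
#'   (from annotated DMR calls).
#' @param norm_mat Normalized expression matrix ([normalize_expression()]).
#' @param samples Sample annotation with state and time_h columns.
#' @param fc_threshold Fold-change cutoff defining up-regulation.
#' @return List with the group split, the two test results and the
#'   fold changes; tests are skipped (NULL, with a note) when a group is
#'   empty.
#' @export
expression_association <- function(dmr_genes, norm_mat, samples,
                                   fc_threshold = 2) {
  dc <- samples$state == "DC"
  genes <- intersect(dmr_genes$gene_id, rownames(norm_mat))
  maxfc <- apply(norm_mat[genes, dc, drop = FALSE], 1, max)
  up <- names(maxfc)[maxfc >= fc_threshold]
  down <- setdiff(genes, up)
  ann <- dmr_genes[match(genes, dmr_genes$gene_id), ]
  grp <- function(ids, col) ann[[col]][ann$gene_id %in% ids]
  run_test <- function(col) {
    if (!length(up) || !length(down)) return(NULL)
    mann_whitney_u(grp(up, col), grp(down, col))
  }
  list(up_genes = up, unchanged_genes = down, max_fold_change = maxfc,
       fc_threshold = fc_threshold,
       cpg_test = run_test("cpg_count"),
       gc_test = run_test("gc_fraction"),
       note = if (!length(up) || !length(down))
         "one group empty; tests skipped" else NULL)
}

#' ChIP-qPCR percent-input normalization and relative enrichment
#'
#' Percent input = 100 * 2^((Ct_input - log2(1/input_fraction)) - Ct_IP):
#' the input Ct is first adjusted for the fraction of chromatin it
#' represents (5% input means +log2(20) cycles of dilution), then the
#' IP quantity is expressed relative to it. Relative enrichment divides
#' each time point's percent input by the 0-h (monocyte) value, so the
#' 0-h sample is exactly 1.
#'
#' @param ct_ip Numeric vector of IP Ct values.
#' @param ct_input Matching input Ct values.
#' @param time_h Time point of each measurement, h.
#' @param input_fraction Fraction of chromatin used as input (default 0.05).
#' @return data.frame of class \code{ChipEnrichment}: time_h,
#'   percent_input, rel_enrichment (NA when no 0-h reference exists).
#' @export
chip_enrichment <- function(ct_ip, ct_input, time_h, input_fraction = 0.05) {
  stopifnot(all(is.finite(ct_ip)), all(is.finite(ct_input)),
            input_fraction > 0, input_fraction <= 1)
  percent_input <- 100 * 2^((ct_input - log2(1 / input_fraction)) - ct_ip)
  ref <- which(time_h == 0)
  rel <- if (length(ref)) percent_input / percent_input[ref[1]]
         else rep(NA_real_, length(ct_ip))
  out <- data.frame(time_h = time_h, percent_input = percent_input,
                    rel_enrichment = rel)
  class(out) <- c("ChipEnrichment", "data.frame")
  out
}
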