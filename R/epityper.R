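#' Average residue masses of the in-vitro transcript alphabet (Da)
#'
#' Internal ribonucleotide-monophosphate residue masses; the only value
#' the quantification depends on is the G - A difference of 16.00 Da,
#' the mass shift carried by each methylated CpG in the reverse-strand
#' T-cleavage reaction.
#' @export
RNA_RESIDUE_MASS <- c(A = 329.21, C = 305.18, G = 345.21, U = 306.17)

#' Terminal-group mass constant added to every cleavage fragment (Da)
#' @export
RNA_TERMINAL_MASS <- 18.02

# standard EpiTYPER primer tags
FORWARD_TAG <- "AGGAAGAGAG"
T7_TAG <- "CAGTAATACGACTCACTATAGGGAGAAGGCT"

#' In-silico sodium bisulfite conversion
#'
#' Every cytosine outside CpG context is converted to thymine; a CpG
#' cytosine is retained as C when methylated and converted to T when
#' unmethylated. Conversion is modelled as complete.
#'
#' @param sequence Character scalar over A/C/G/T.
#' @param meth_flags Logical vector, one entry per CpG cytosine of the
#'   sequence in left-to-right order.
#' @return The converted sequence.
#' @export
bisulfite_convert <- function(sequence, meth_flags = logical(0)) {
  b <- strsplit(toupper(sequence), "")[[1]]
  n <- length(b)
  is_c <- b == "C"
  in_cpg <- is_c & c(b[-1] == "G", FALSE)
  if (length(meth_flags) != sum(in_cpg))
    stop_config("meth_flags has %d entries but the sequence has %d CpG cytosines",
                length(meth_flags), sum(in_cpg))
  b[is_c & !in_cpg] <- "T"
  cpg_idx <- which(in_cpg)
  b[cpg_idx[!meth_flags]] <- "T"
  paste(b, collapse = "")
}

#' Design a bisulfite amplicon over a genomic region
#'
#' The forward primer carries a 10-mer tag; the reverse primer carries
#' the T7 promoter tag so that in vitro transcription runs off the
#' reverse strand of the PCR product.
#'
#' @param genome A \code{GenomeModel}.
#' @param chrom,start,end Region coordinates (0-based half-open).
#' @param region_id Identifier stored with the amplicon.
#' @param len_bounds Allowed amplicon length range, bp.
#' @param primer_len Length of the genomic part of each primer.
#' @return A \code{BisulfiteAmplicon}: list with region coords, sequence,
#'   relative 1-based CpG positions, and tagged primers.
#' @export
design_amplicon <- function(genome, chrom, start, end, region_id = NULL,
                            len_bounds = c(200L, 600L), primer_len = 20L) {
  len <- end - start
  if (len < len_bounds[1] || len > len_bounds[2])
    stop_config("amplicon length %d outside bounds [%d, %d]",
                len, len_bounds[1], len_bounds[2])
  seq <- genome_window_seq(genome, chrom, start, end)
  b <- strsplit(seq, "")[[1]]
  cpg_pos <- which(b[-length(b)] == "C" & b[-1] == "G")
  structure(list(region_id = region_id %||% sprintf("%s:%d-%d", chrom, start, end),
                 chrom = chrom, start = start, end = end, sequence = seq,
                 cpg_pos = cpg_pos,
                 fwd_primer = paste0(FORWARD_TAG, substr(seq, 1, primer_len)),
                 rev_primer = paste0(T7_TAG, revcomp(substr(seq, len - primer_len + 1, len)))),
            class = "BisulfiteAmplicon")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

#' Base-specific T-cleavage of the reverse-strand transcript
#'
#' The transcript is the RNA copy of the bisulfite-converted amplicon's
#' reverse strand; at a forward-strand CpG the transcript reads G when
#' the CpG was methylated (C retained) and A when it was unmethylated
#' (C converted to T). Uracils in the transcript stem from
#' methylation-independent positions (forward-strand adenines), so the
#' T-cleavage reaction — which cuts 3' of every U — yields a fragment
#' pattern that does not depend on methylation; only fragment masses do.
#' CpGs falling into the same fragment form one CpG unit and are
#' quantified jointly.
#'
#' @param amplicon A \code{BisulfiteAmplicon}.
#' @param reaction Cleavage reaction; only "T" is supported.
#' @return List of \code{CleavageFragment}s: each with the fragment
#'   residue sequence (unmethylated reading), its transcript span, the
#'   indices of amplicon CpGs it contains, and masses for methylation
#'   counts k = 0..n_cpg.
#' @export
cleave_transcript <- function(amplicon, reaction = "T") {
  if (!identical(reaction, "T"))
    stop_config("unsupported cleavage reaction '%s' (only T is modelled)",
                reaction)
  # unmethylated reference conversion fixes the cleavage pattern
  conv <- bisulfite_convert(amplicon$sequence,
                            rep(FALSE, length(amplicon$cpg_pos)))
  transcript <- to_rna(revcomp(conv))
  L <- nchar(transcript)
  # transcript coordinate of the base complementary to each CpG cytosine
  cpg_t <- L - amplicon$cpg_pos + 1L
  frags <- split_after_u(transcript)
  out <- list()
  off <- 0L
  for (i in seq_along(frags)) {
    fseq <- frags[[i]]
    span <- c(off + 1L, off + nchar(fseq))
    members <- which(cpg_t >= span[1] & cpg_t <= span[2])
    n <- length(members)
    base_mass <- sum(RNA_RESIDUE_MASS[strsplit(fseq, "")[[1]]]) +
      RNA_TERMINAL_MASS
    masses <- base_mass + (0:n) *
      (RNA_RESIDUE_MASS[["G"]] - RNA_RESIDUE_MASS[["A"]])
    out[[i]] <- structure(list(fragment_id = i, sequence = fseq,
                               span = span, cpg_members = members,
                               n_cpg = n, masses = masses),
                          class = "CleavageFragment")
    off <- span[2]
  }
  out
}

to_rna <- function(s) gsub("T", "U", toupper(s))

# split a transcript 3' of every U, keeping order
split_after_u <- function(transcript) {
  m <- gregexpr("[^U]*U|[^U]+$", transcript)[[1]]
  regmatches(transcript, list(m))[[1]]
}

#' Mass of a cleavage fragment at a given methylation count
#'
#' Sum of per-residue masses (unmethylated reading) plus the terminal
#' constant, shifted by the G - A residue difference (16.00 Da) for each
#' methylated CpG the fragment carries.
#'
#' @param fragment A \code{CleavageFragment}.
#' @param k Number of methylated CpGs, 0..n_cpg.
#' @return Mass in Da.
#' @export
fragment_mass <- function(fragment, k = 0L) {
  if (!nchar(fragment$sequence)) stop_config("empty cleavage fragment")
  if (k < 0 || k > fragment$n_cpg)
    stop_config("k = %d outside 0..%d", k, fragment$n_cpg)
  fragment$masses[[k + 1L]]
}

# Poisson-binomial pmf of the number of methylated CpGs in a unit given
# independent per-CpG population fractions
pois_binom_pmf <- function(p) {
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  pmf
}

#' Simulate MALDI-TOF peak intensities for the CpG units of an amplicon
#'
#' Peak intensity of the k-methylated species of a unit is proportional
#' to the population probability of k methylated CpGs (independent
#' per-CpG fractions), times multiplicative lognormal noise.
#'
#' @param fragments Output of [cleave_transcript()].
#' @param fractions Population methylation fractions of the amplicon's
#'   CpGs (aligned with \code{amplicon$cpg_pos}).
#' @param noise_sd SD of the lognormal intensity noise (0 = noiseless).
#' @param seed Integer seed.
#' @return List (per CpG-bearing fragment) of intensity vectors I_0..I_n.
#' @export
simulate_unit_intensities <- function(fragments, fractions, noise_sd = 0.1,
                                      seed = 1L) {
  set.seed(seed)
  lapply(fragments, function(fr) {
    if (fr$n_cpg == 0) return(numeric(0))
    pmf <- pois_binom_pmf(fractions[fr$cpg_members])
    if (noise_sd > 0)
      pmf <- pmf * rlnorm(length(pmf), -noise_sd^2 / 2, noise_sd)
    pmf
  })
}

#' Quantify per-CpG-unit methylation ratios from peak intensities
#'
#' For a measurable unit with n CpGs and peak intensities I_0..I_n the
#' ratio is sum(k * I_k) / (n * sum(I_k)). A unit is unmeasurable — and
#' never silently quantified — when any of its peaks falls outside the
#' detection window or within \code{mass_resolution} Da of a peak
#' belonging to a different fragment (mass collision).
#'
#' @param fragments Output of [cleave_transcript()].
#' @param intensities Output of [simulate_unit_intensities()].
#' @param detection_window Mass window in Da.
#' @param mass_resolution Minimum peak separation in Da.
#' @return A \code{CpGUnitMeasurement} data.frame: unit_id, fragment_id,
#'   n_cpg, member CpG indices (comma-separated), measurable flag, ratio.
#' @export
quantify_units <- function(fragments, intensities,
                           detection_window = c(1500, 7000),
                           mass_resolution = 0.5) {
  cpg_frags <- which(vapply(fragments, function(f) f$n_cpg > 0, logical(1)))
  all_masses <- data.frame(
    fragment_id = rep(vapply(fragments, `[[`, 0L, "fragment_id"),
                      vapply(fragments, function(f) f$n_cpg + 1L, integer(1))),
    mass = unlist(lapply(fragments, `[[`, "masses")))
  out <- list()
  for (i in cpg_frags) {
    fr <- fragments[[i]]
    I <- intensities[[i]]
    in_window <- all(fr$masses >= detection_window[1] &
                     fr$masses <= detection_window[2])
    other <- all_masses$mass[all_masses$fragment_id != fr$fragment_id]
    collision <- any(vapply(fr$masses,
      function(m) any(abs(other - m) < mass_resolution), logical(1)))
    measurable <- in_window && !collision
    ratio <- NA_real_
    if (measurable) {
      tot <- sum(I)
      if (tot <= 0) {
        measurable <- FALSE
      } else {
        ratio <- sum((seq_along(I) - 1) * I) / (fr$n_cpg * tot)
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      unit_id = sprintf("unit%02d", length(out) + 1L),
      fragment_id = fr$fragment_id, n_cpg = fr$n_cpg,
      cpg_members = paste(fr$cpg_members, collapse = ","),
      measurable = measurable, ratio = ratio,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(unit_id = character(0), fragment_id = integer(0),
               n_cpg = integer(0), cpg_members = character(0),
               measurable = logical(0), ratio = numeric(0))
  class(res) <- c("CpGUnitMeasurement", "data.frame")
  res
}

#' Run the EpiTYPER-style workflow over a set of regions
#'
#' For each region and cell state: design the amplicon, cleave the
#' reverse-strand transcript, simulate peak intensities from the
#' per-CpG population fractions, and quantify per-unit ratios.
#'
#' @param genome A \code{GenomeModel}.
#' @param methylome A \code{MethylomeState}.
#' @param regions data.frame with region_id, chrom, start, end.
#' @param states Cell states to assay.
#' @param time_h Time point for the DC/MAC states.
#' @param noise_sd Peak-intensity noise SD.
#' @param seed Integer seed.
#' @param len_bounds Amplicon length bounds passed to [design_amplicon()].
#' @return data.frame of per-unit ratios: region_id, state, unit_id,
#'   n_cpg, measurable, ratio.
#' @export
simulate_epityper <- function(genome, methylome, regions,
                              states = c("DC", "MAC"), time_h = 168,
                              noise_sd = 0.1, seed = 1L,
                              len_bounds = c(200L, 600L)) {
  out <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    amp <- design_amplicon(genome, r$chrom, r$start, r$end,
                           region_id = r$region_id, len_bounds = len_bounds)
    frags <- cleave_transcript(amp)
    in_amp <- which(methylome$sites$chrom == r$chrom &
                    methylome$sites$pos >= r$start &
                    methylome$sites$pos < r$end)
    # align methylome sites with the amplicon's CpG list
    amp_abs <- r$start + amp$cpg_pos - 1L
    for (st in states) {
      frac_all <- methylation_fraction(methylome, st, time_h)
      fr <- frac_all[in_amp][match(amp_abs, methylome$sites$pos[in_amp])]
      fr[is.na(fr)] <- 0
      ints <- simulate_unit_intensities(frags, fr, noise_sd,
        seed = child_seed(seed, i * 13L + match(st, states)))
      units <- quantify_units(frags, ints)
      if (nrow(units)) {
        units$region_id <- r$region_id
        units$state <- st
        out[[length(out) + 1L]] <- units
      }
    }
  }
  if (!length(out))
    return(data.frame(region_id = character(0), state = character(0),
                      unit_id = character(0), n_cpg = integer(0),
                      measurable = logical(0), ratio = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("region_id", "state", "unit_id", "fragment_id", "n_cpg",
          "cpg_members", "measurable", "ratio")]
}

#' Concordance between array DMR calls and mass-spec methylation ratios
#'
#' A region called differentially methylated on the array is concordant
#' when the sign of (MAC mean ratio - DC mean ratio) matches the array
#' direction; an array-negative control region is concordant when the
#' two assays agree that there is no difference, |MAC - DC| <
#' \code{delta_min}.
#'
#' @param array_calls data.frame with region_id and direction
#'   ("hypomethylated-in-DC", "hypomethylated-in-MAC", or "none" for
#'   control regions).
#' @param ms_means data.frame with region_id, mean_dc, mean_mac (mean
#'   measurable-unit ratios per state).
#' @param delta_min Ratio difference below which two assays agree on "no
#'   difference".
#' @return List with n_regions, n_concordant, pct_concordant and the
#'   per-region table.
#' @export
assess_concordance <- function(array_calls, ms_means, delta_min = 0.1) {
  stopifnot(delta_min >= 0)
  tab <- merge(array_calls, ms_means, by = "region_id")
  if (!nrow(tab))
    stop_config("no regions shared between array calls and MS measurements")
  d <- tab$mean_mac - tab$mean_dc
  tab$concordant <- ifelse(tab$direction == "hypomethylated-in-DC", d > 0,
                    ifelse(tab$direction == "hypomethylated-in-MAC", d < 0,
                           abs(d) < delta_min))
  list(n_regions = nrow(tab),
       n_concordant = sum(tab$concordant),
       pct_concordant = 100 * mean(tab$concordant),
       table = tab)
}
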