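#' Configuration for synthetic genome generation
#'
#' Builds the parameter list consumed by [generate_genome()]. The defaults
#' describe a desk-scale genome: two 100-kb chromosomes carrying 20 genes
#' whose promoters (strand-aware -4,000..+1,000 bp around the TSS) are
#' tiled by the simulated promoter array. Promoters are assigned a CpG
#' density class; the array's target regions are of low to intermediate
#' CpG content, so no CpG-island-like class is modelled.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome in bp.
#' @param n_genes Total number of genes to place.
#' @param bg_cpg_density Background CpG dinucleotide density per bp.
#' @param promoter_cpg_density Named vector of per-class CpG densities
#'   (per bp) for promoter windows.
#' @param p_intermediate Probability that a promoter is of the
#'   intermediate CpG-density class (otherwise low).
#' @param promoter_up,promoter_down Promoter window extent upstream /
#'   downstream of the TSS in transcription direction, bp.
#' @param gene_len_range Range of gene body lengths, bp.
#' @param overlap_allowance Maximum tolerated overlap (bp) between two
#'   promoter windows during gene placement.
#' @param gc_content Base-level G+C fraction of the background sequence.
#' @param n_cpg_clusters Number of dispersed low-CpG-density clusters
#'   planted per chromosome outside promoter windows. Intragenic and
#'   intergenic regions of elevated CpG density are where non-promoter
#'   DMRs live; the flat background between them is too CpG-poor to be
#'   differentially methylated in any meaningful sense.
#' @param cluster_width Width of each dispersed CpG cluster, bp.
#' @param cluster_cpg_density CpG density inside dispersed clusters,
#'   per bp (defaults to the low promoter class).
#' @return A list of class \code{genome_config}.
#' @export
genome_config <- function(n_chrom = 2L,
                          chrom_len = 100000L,
                          n_genes = 20L,
                          bg_cpg_density = 0.01,
                          promoter_cpg_density = c(low = 0.02, intermediate = 0.05),
                          p_intermediate = 0.3,
                          promoter_up = 4000L,
                          promoter_down = 1000L,
                          gene_len_range = c(2000L, 8000L),
                          overlap_allowance = 0L,
                          gc_content = 0.42,
                          n_cpg_clusters = 15L,
                          cluster_width = 600L,
                          cluster_cpg_density = 0.02) {
  stopifnot(n_chrom >= 1, chrom_len > 0, n_genes >= 0,
            bg_cpg_density >= 0, all(promoter_cpg_density >= 0),
            p_intermediate >= 0, p_intermediate <= 1)
  structure(list(n_chrom = as.integer(n_chrom),
                 chrom_len = as.integer(chrom_len),
                 n_genes = as.integer(n_genes),
                 bg_cpg_density = bg_cpg_density,
                 promoter_cpg_density = promoter_cpg_density,
                 p_intermediate = p_intermediate,
                 promoter_up = as.integer(promoter_up),
                 promoter_down = as.integer(promoter_down),
                 gene_len_range = as.integer(gene_len_range),
                 overlap_allowance = as.integer(overlap_allowance),
                 gc_content = gc_content,
                 n_cpg_clusters = as.integer(n_cpg_clusters),
                 cluster_width = as.integer(cluster_width),
                 cluster_cpg_density = cluster_cpg_density),
            class = "genome_config")
}

# sample a background base vector with no CpG dinucleotides, then plant
# CpGs at the requested density at uniform positions
random_chrom_seq <- function(len, cpg_density, gc_content) {
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  s <- sample(names(p), len, replace = TRUE, prob = p)
  s <- scrub_cpgs(s)
  plant_cpgs(s, round(cpg_density * len))
}

# destroy every CG dinucleotide by rewriting its G as A
scrub_cpgs <- function(s) {
  i <- which(s[-length(s)] == "C" & s[-1] == "G")
  if (length(i)) s[i + 1L] <- "A"
  s
}

# plant n_cpg non-adjacent CG dinucleotides at uniform positions; planting
# C at p and G at p+1 cannot create a second CG as long as plant positions
# are >= 2 bp apart
plant_cpgs <- function(s, n_cpg, lo = 1L, hi = length(s) - 1L) {
  if (n_cpg <= 0 || hi < lo) return(s)
  cand <- seq.int(lo, hi)
  pos <- integer(0)
  # greedy thinning to enforce >= 2 bp spacing
  picks <- sample(cand, min(length(cand), 4L * n_cpg + 16L))
  for (p in picks) {
    if (length(pos) == n_cpg) break
    if (!length(pos) || min(abs(pos - p)) >= 2L) pos <- c(pos, p)
  }
  s[pos] <- "C"
  s[pos + 1L] <- "G"
  s
}

# strand-aware promoter window in 0-based half-open genome coordinates
promoter_interval <- function(tss, strand, up, down) {
  if (strand == "+") c(tss - up, tss + down + 1L) else c(tss - down, tss + up + 1L)
}

#' Generate a seeded synthetic genome with TSS-annotated promoters
#'
#' Produces random chromosome sequences with a controlled background CpG
#' dinucleotide density, places non-overlapping genes, and re-plants CpGs
#' inside each promoter window at the density of its assigned CpG class
#' (low or intermediate). All coordinates are 0-based half-open.
#'
#' @param config A [genome_config()] list.
#' @param seed Integer seed; the same config + seed yields a bit-identical
#'   genome.
#' @return An object of class \code{GenomeModel}: a list with
#'   \code{seqs} (a [Biostrings::DNAStringSet]), \code{genes} (a
#'   data.frame with gene_id, chrom, tss, strand, start, end, cpg_class),
#'   and the generating \code{config}.
#' @export
generate_genome <- function(config = genome_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
  seqs <- lapply(chroms, function(ch)
    random_chrom_seq(cfg$chrom_len, cfg$bg_cpg_density, cfg$gc_content))
  names(seqs) <- chroms

  genes <- place_genes(cfg, chroms)
  if (nrow(genes)) {
    cls <- ifelse(runif(nrow(genes)) < cfg$p_intermediate, "intermediate", "low")
    genes$cpg_class <- cls
    for (i in seq_len(nrow(genes))) {
      w <- promoter_interval(genes$tss[i], genes$strand[i],
                             cfg$promoter_up, cfg$promoter_down)
      w[1] <- max(w[1], 0L); w[2] <- min(w[2], cfg$chrom_len)
      ch <- genes$chrom[i]
      idx <- seq.int(w[1] + 1L, w[2])        # 1-based slice
      seg <- scrub_cpgs(seqs[[ch]][idx])
      dens <- cfg$promoter_cpg_density[[genes$cpg_class[i]]]
      seg <- plant_cpgs(seg, round(dens * length(seg)))
      seqs[[ch]][idx] <- seg
    }
  } else {
    genes$cpg_class <- character(0)
  }

  # dispersed CpG clusters outside promoter windows
  clusters <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
  if (cfg$n_cpg_clusters > 0) {
    prom <- lapply(seq_len(nrow(genes)), function(i) {
      w <- promoter_interval(genes$tss[i], genes$strand[i],
                             cfg$promoter_up, cfg$promoter_down)
      c(list(chrom = genes$chrom[i]), list(w = w))
    })
    for (ch in chroms) {
      placed <- 0L; tries <- 0L
      pw <- Filter(function(p) p$chrom == ch, prom)
      while (placed < cfg$n_cpg_clusters && tries < 200L * cfg$n_cpg_clusters) {
        tries <- tries + 1L
        st <- sample.int(cfg$chrom_len - cfg$cluster_width, 1L)
        en <- st + cfg$cluster_width
        clash <- any(vapply(pw, function(p)
          st < p$w[2] && en > p$w[1], logical(1)))
        if (clash) next
        if (nrow(clusters) &&
            any(clusters$chrom == ch & st < clusters$end + 1000L &
                en > clusters$start - 1000L)) next
        idx <- seq.int(st + 1L, en)
        seg <- scrub_cpgs(seqs[[ch]][idx])
        seg <- plant_cpgs(seg, round(cfg$cluster_cpg_density * length(seg)))
        seqs[[ch]][idx] <- seg
        clusters <- rbind(clusters, data.frame(
          chrom = ch, start = as.integer(st), end = as.integer(en),
          stringsAsFactors = FALSE))
        placed <- placed + 1L
      }
    }
  }

  dss <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  structure(list(seqs = dss, genes = genes, cpg_clusters = clusters,
                 config = cfg, seed = seed),
            class = "GenomeModel")
}

# rejection-sampling gene placement honouring the promoter-overlap allowance
place_genes <- function(cfg, chroms) {
  genes <- data.frame(gene_id = character(0), chrom = character(0),
                      tss = integer(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (cfg$n_genes == 0L) return(genes)
  placed <- vector("list", 0)
  margin <- cfg$promoter_up + cfg$promoter_down + 2L
  if (cfg$chrom_len <= 2L * margin)
    stop_config("chromosomes of %d bp cannot hold a %d-bp promoter window",
                cfg$chrom_len, margin)
  tries <- 0L; max_tries <- cfg$n_genes * 500L
  while (nrow(genes) < cfg$n_genes) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop_config("could not place %d genes without promoter overlap > %d bp; reduce n_genes or increase chrom_len",
                  cfg$n_genes, cfg$overlap_allowance)
    ch <- sample(chroms, 1L)
    strand <- sample(c("+", "-"), 1L)
    glen <- sample(seq(cfg$gene_len_range[1], cfg$gene_len_range[2]), 1L)
    tss <- sample.int(cfg$chrom_len - 2L * margin, 1L) + margin
    if (strand == "+") { gstart <- tss; gend <- tss + glen }
    else { gend <- tss + 1L; gstart <- gend - glen }
    if (gstart < 0L || gend > cfg$chrom_len) next
    w <- promoter_interval(tss, strand, cfg$promoter_up, cfg$promoter_down)
    ok <- TRUE
    for (p in placed) {
      if (p$chrom != ch) next
      ov <- min(w[2], p$w[2]) - max(w[1], p$w[1])
      if (ov > cfg$overlap_allowance) { ok <- FALSE; break }
    }
    if (!ok) next
    placed[[length(placed) + 1L]] <- list(chrom = ch, w = w)
    genes <- rbind(genes, data.frame(
      gene_id = sprintf("gene%03d", nrow(genes) + 1L), chrom = ch,
      tss = as.integer(tss), strand = strand,
      start = as.integer(gstart), end = as.integer(gend),
      stringsAsFactors = FALSE))
  }
  genes
}

#' Promoter windows of a genome as a GRanges
#'
#' @param genome A \code{GenomeModel}.
#' @return A [GenomicRanges::GRanges] of strand-aware promoter windows
#'   (clipped to chromosome bounds) with a \code{gene_id} column.
#' @export
promoter_windows <- function(genome) {
  cfg <- genome$config
  g <- genome$genes
  if (!nrow(g)) return(GenomicRanges::GRanges())
  w <- t(mapply(promoter_interval, g$tss, g$strand,
                MoreArgs = list(up = cfg$promoter_up, down = cfg$promoter_down)))
  w[, 1] <- pmax(w[, 1], 0L)
  w[, 2] <- pmin(w[, 2], cfg$chrom_len)
  gr <- GenomicRanges::GRanges(g$chrom,
                               IRanges::IRanges(start = w[, 1] + 1L, end = w[, 2]),
                               strand = g$strand)
  gr$gene_id <- g$gene_id
  gr
}

#' Locate all CpG dinucleotides in a genome
#'
#' @param genome A \code{GenomeModel}.
#' @return data.frame with \code{chrom} and 0-based \code{pos} of the C of
#'   each CpG, ordered by chromosome and position.
#' @export
cpg_sites <- function(genome) {
  out <- lapply(names(genome$seqs), function(ch) {
    m <- Biostrings::matchPattern("CG", genome$seqs[[ch]])
    data.frame(chrom = ch, pos = BiocGenerics::start(m) - 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write genome sequences as FASTA
#' @param genome A \code{GenomeModel}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path)
  invisible(path)
}

#' Write TSS records as BED6
#'
#' One record per gene; the name field is the gene id, the strand column
#' carries the transcription direction.
#' @param genome A \code{GenomeModel}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_tss_bed <- function(genome, path) {
  g <- genome$genes
  gr <- GenomicRanges::GRanges(g$chrom,
                               IRanges::IRanges(start = g$tss + 1L, width = 1L),
                               strand = g$strand)
  gr$name <- g$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# extract a 1-based-inclusive window as a character string, clipped
genome_window_seq <- function(genome, chrom, start0, end0) {
  len <- length(genome$seqs[[chrom]])
  s <- max(start0, 0L) + 1L
  e <- min(end0, len)
  as.character(Biostrings::subseq(genome$seqs[[chrom]], s, e))
}
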