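#' Simulation configuration for synthetic NET-seq data
#'
#' Parameterizes the statistical structure the downstream analysis assumes:
#' negative-binomial background counts, stereotypical single-nucleotide pauses
#' whose strengths are rank-correlated between two replicates plus
#' replicate-specific noise pauses, and antisense transcription over the
#' 3'-terminal half of a fraction of genes.
#'
#' @param n_genes number of sense transcription units.
#' @param gene_length_range bp pair (min, max); min must be >= 600 bp so the
#'   largest region-index window fits inside a gene.
#' @param intergenic_gap bp between consecutive units.
#' @param intron_fraction proportion of genes carrying one intron.
#' @param expression_mean_range reads/bp pair; per-gene background mean is
#'   drawn uniformly from this range and shared between replicates.
#' @param nb_dispersion negative-binomial size parameter r of the background
#'   (variance = mean + mean^2 / r).
#' @param pause_rate planted pauses per kb of gene (default 30, matching the
#'   one-pause-per-33-bp density observed in wild-type yeast NET-seq).
#' @param pause_strength_range fold-over-background pair for planted pauses.
#' @param reproducible_fraction proportion of planted pauses present in both
#'   replicates.
#' @param antisense_fraction proportion of genes with an antisense unit.
#' @param strength_noise_sd sd of the i.i.d. log-normal noise added to the
#'   shared latent log-strength in each replicate (gives the rank-correlated
#'   replicate structure the IDR model assumes).
#' @param antisense_expression_factor antisense background mean as a fraction
#'   of the host gene's mean.
#' @param n_chrom,chrom_length toy genome shape (default 2 x 150 kb).
#' @param gc GC content of the i.i.d. genome sequence.
#' @param seed integer seed; every generator is deterministic given the seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 200,
                              gene_length_range = c(600, 1400),
                              intergenic_gap = 150,
                              intron_fraction = 0.25,
                              expression_mean_range = c(1, 10),
                              nb_dispersion = 10,
                              pause_rate = 30,
                              pause_strength_range = c(5, 15),
                              reproducible_fraction = 0.7,
                              antisense_fraction = 0.3,
                              strength_noise_sd = 0.2,
                              antisense_expression_factor = 0.2,
                              n_chrom = 2,
                              chrom_length = 150000,
                              gc = 0.38,
                              seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              gene_length_range = as.numeric(gene_length_range),
              intergenic_gap = as.integer(intergenic_gap),
              intron_fraction = intron_fraction,
              expression_mean_range = as.numeric(expression_mean_range),
              nb_dispersion = nb_dispersion,
              pause_rate = pause_rate,
              pause_strength_range = as.numeric(pause_strength_range),
              reproducible_fraction = reproducible_fraction,
              antisense_fraction = antisense_fraction,
              strength_noise_sd = strength_noise_sd,
              antisense_expression_factor = antisense_expression_factor,
              n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length),
              gc = gc,
              seed = as.integer(seed))
  for (p in c("intron_fraction", "reproducible_fraction", "antisense_fraction", "gc"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  if (cfg$gene_length_range[1] < 600)
    stop("gene_length_range minimum must be >= 600 bp (largest index window)")
  if (cfg$pause_rate < 0) stop("pause_rate must be >= 0")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate a toy genome and annotation
#'
#' Draws an i.i.d. nucleotide sequence at the configured GC content and lays
#' non-overlapping transcription units (random strand) along each chromosome,
#' separated by `intergenic_gap`, each with a TSS, poly(A) site and, for
#' `intron_fraction` of genes, one intron with 5'/3' splice sites.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` (a [Biostrings::DNAStringSet]) and `annotation`
#'   (a [tx_annotation()] of sense units).
#' @export
generate_toy_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
             G = config$gc / 2, T = (1 - config$gc) / 2)
  chroms <- paste0("chrS", seq_len(config$n_chrom))
  seqs <- vapply(chroms, function(ch)
    paste(sample(names(probs), config$chrom_length, replace = TRUE, prob = probs),
          collapse = ""), character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms

  lens <- as.integer(round(runif(config$n_genes, config$gene_length_range[1],
                                 config$gene_length_range[2])))
  strands <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  has_intron <- runif(config$n_genes) < config$intron_fraction
  chrom_of <- rep(chroms, length.out = config$n_genes)

  rows <- vector("list", config$n_genes)
  cursor <- setNames(rep(config$intergenic_gap, config$n_chrom), chroms)
  for (i in seq_len(config$n_genes)) {
    ch <- chrom_of[i]
    start <- cursor[[ch]]
    end <- start + lens[i]
    if (end + config$intergenic_gap > config$chrom_length)
      stop(sprintf(
        "gene budget exceeds chromosome length: gene %d needs [%d, %d) on %s (length %d)",
        i, start, end, ch, config$chrom_length))
    cursor[[ch]] <- end + config$intergenic_gap
    intron <- c(NA_integer_, NA_integer_)
    if (has_intron[i]) {
      ilen <- as.integer(round(runif(1, 60, 200)))
      ioff <- as.integer(round(0.3 * lens[i]))
      intron <- c(start + ioff, start + ioff + ilen)
    }
    rows[[i]] <- data.frame(
      gene_id = sprintf("gene%04d", i), chrom = ch,
      start = start, end = end, strand = strands[i],
      tss = if (strands[i] == "+") start else end - 1L,
      polya = if (strands[i] == "+") end - 1L else start,
      intron_start = intron[1], intron_end = intron[2],
      type = "gene", stringsAsFactors = FALSE)
  }
  list(genome = genome, annotation = tx_annotation(do.call(rbind, rows)))
}

#' Simulate two replicate occupancy tracks with planted pauses
#'
#' Background counts at every gene position are drawn NB(mean = the gene's
#' expression level, size = `nb_dispersion`). Planted pause positions are
#' drawn uniformly within genes at `pause_rate` per kb; each pause has a
#' latent fold-strength and, per replicate, a count drawn Poisson with mean
#' (latent strength x log-normal replicate noise) x gene mean, replacing the
#' background draw at that position. A `reproducible_fraction` of pauses
#' appears in both replicates; the rest in one randomly chosen replicate.
#' Antisense signal (independent NB background at
#' `antisense_expression_factor` x host mean) is laid on the opposite strand
#' over the 3'-terminal half of a deterministic `antisense_fraction` subset of
#' genes.
#'
#' @param annotation Sense annotation from [generate_toy_genome()].
#' @param config The same [simulation_config()].
#' @return List with `rep1`, `rep2` (raw [occupancy_track()]s) and `truth`, a
#'   data frame of planted pauses (`chrom`, `pos` 0-based, `strand`,
#'   `gene_id`, `planted_strength`, `reproducible`, `expression`).
#' @export
simulate_occupancy <- function(annotation, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  n <- nrow(annotation)
  expr <- runif(n, config$expression_mean_range[1], config$expression_mean_range[2])
  anti <- runif(n) < config$antisense_fraction

  counts1 <- vector("list", 2L * n)
  counts2 <- vector("list", 2L * n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    len <- annotation$end[i] - annotation$start[i]
    gpos <- seq.int(annotation$start[i], annotation$end[i] - 1L)
    bg1 <- rnbinom(len, mu = expr[i], size = config$nb_dispersion)
    bg2 <- rnbinom(len, mu = expr[i], size = config$nb_dispersion)

    n_pause <- rpois(1, config$pause_rate * len / 1000)
    n_pause <- min(n_pause, len)
    if (n_pause > 0) {
      at <- sample.int(len, n_pause)
      latent <- runif(n_pause, config$pause_strength_range[1],
                      config$pause_strength_range[2])
      repro <- runif(n_pause) < config$reproducible_fraction
      which_rep <- sample(1:2, n_pause, replace = TRUE)  # for irreproducible ones
      s1 <- latent * exp(rnorm(n_pause, 0, config$strength_noise_sd))
      s2 <- latent * exp(rnorm(n_pause, 0, config$strength_noise_sd))
      in1 <- repro | which_rep == 1L
      in2 <- repro | which_rep == 2L
      bg1[at[in1]] <- rpois(sum(in1), s1[in1] * expr[i])
      bg2[at[in2]] <- rpois(sum(in2), s2[in2] * expr[i])
      truth[[i]] <- data.frame(
        chrom = annotation$chrom[i], pos = gpos[at],
        strand = annotation$strand[i], gene_id = annotation$gene_id[i],
        planted_strength = latent, reproducible = repro,
        expression = expr[i], stringsAsFactors = FALSE)
    }
    counts1[[i]] <- data.frame(chrom = annotation$chrom[i], pos = gpos,
                               strand = annotation$strand[i], count = bg1)
    counts2[[i]] <- data.frame(chrom = annotation$chrom[i], pos = gpos,
                               strand = annotation$strand[i], count = bg2)
    if (anti[i]) {
      astrand <- if (annotation$strand[i] == "+") "-" else "+"
      half <- if (annotation$strand[i] == "+") {
        seq.int(annotation$start[i] + len %/% 2L, annotation$end[i] - 1L)
      } else {
        seq.int(annotation$start[i], annotation$start[i] + len %/% 2L)
      }
      amu <- config$antisense_expression_factor * expr[i]
      counts1[[n + i]] <- data.frame(chrom = annotation$chrom[i], pos = half,
                                     strand = astrand,
                                     count = rnbinom(length(half), mu = amu,
                                                     size = config$nb_dispersion))
      counts2[[n + i]] <- data.frame(chrom = annotation$chrom[i], pos = half,
                                     strand = astrand,
                                     count = rnbinom(length(half), mu = amu,
                                                     size = config$nb_dispersion))
    }
  }
  truth <- if (length(tr <- Filter(Negate(is.null), truth))) {
    do.call(rbind, tr)
  } else {
    data.frame(chrom = character(), pos = integer(), strand = character(),
               gene_id = character(), planted_strength = numeric(),
               reproducible = logical(), expression = numeric())
  }
  rownames(truth) <- NULL
  list(rep1 = occupancy_track(do.call(rbind, Filter(Negate(is.null), counts1))),
       rep2 = occupancy_track(do.call(rbind, Filter(Negate(is.null), counts2))),
       truth = truth)
}

#' Simulate exon-junction read counts
#'
#' Per intron, reads spanning the junction by at least the overhang rule are
#' classified as spliced or unspliced at either splice site; counts are
#' multinomial with spliced proportion `psi` and the unspliced remainder split
#' evenly between the 5' and 3' splice sites.
#'
#' @param annotation A [tx_annotation()]; only intron-bearing units are used.
#' @param psi spliced proportion in `[0, 1]`, scalar or one value per intron.
#' @param depth junction reads per intron.
#' @param seed integer seed.
#' @return Data frame with `intron_id`, `spliced`, `unspliced5`, `unspliced3`.
#' @export
simulate_junction_counts <- function(annotation, psi, depth, seed = 1) {
  ann <- annotation[!is.na(annotation$intron_start), , drop = FALSE]
  if (!nrow(ann)) stop("annotation has no introns")
  if (any(psi < 0 | psi > 1)) stop("psi must be in [0, 1]")
  psi <- rep_len(psi, nrow(ann))
  set.seed(seed)
  counts <- vapply(seq_len(nrow(ann)), function(i)
    as.numeric(rmultinom(1, depth, c(psi[i], (1 - psi[i]) / 2, (1 - psi[i]) / 2))),
    numeric(3))
  data.frame(intron_id = paste0(ann$gene_id, "_intron"),
             spliced = counts[1, ], unspliced5 = counts[2, ],
             unspliced3 = counts[3, ], stringsAsFactors = FALSE)
}

# The 6 genomic bases immediately downstream (in transcript orientation) of a
# 3'-end position, returned in nascent-RNA sense. NA when the window runs off
# the chromosome.
adjacent_hexamer <- function(genome, chrom, pos, strand) {
  if (length(chrom) == 1) chrom <- rep(chrom, length(pos))
  if (length(strand) == 1) strand <- rep(strand, length(pos))
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  out <- rep(NA_character_, length(pos))
  plus <- strand == "+"
  ok_p <- plus & pos + 6 < len
  ok_m <- !plus & pos - 6 >= 0
  if (any(ok_p))
    out[ok_p] <- as.character(Biostrings::subseq(
      genome[chrom[ok_p]], start = pos[ok_p] + 2L, width = 6L))
  if (any(ok_m))
    out[ok_m] <- as.character(Biostrings::reverseComplement(Biostrings::subseq(
      genome[chrom[ok_m]], start = pos[ok_m] - 5L, width = 6L)))
  out
}

#' Simulate reads with hexamer molecular barcodes and RT-mispriming artifacts
#'
#' Draws 3'-end positions uniformly within genes, builds read records on the
#' opposite (alignment) strand per the fr-firststrand convention, and attaches
#' a hexamer barcode: for `misprime_fraction` of reads, the barcode equals the
#' 6 genomic bases immediately downstream (transcript orientation) of the 3'
#' end, mimicking internal reverse-transcription priming; the rest get random
#' hexamers (chance collisions are left in, matching real-data behavior).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param annotation A [tx_annotation()].
#' @param n_reads number of reads.
#' @param misprime_fraction proportion of misprimed reads.
#' @param read_length aligned read length (bp).
#' @param seed integer seed.
#' @return A `read_records` data frame (`chrom`, `start`, `end` 0-based
#'   half-open, `alignment_strand`, `barcode`).
#' @export
simulate_misprimed_reads <- function(genome, annotation, n_reads = 1000,
                                     misprime_fraction = 0, read_length = 50,
                                     seed = 1) {
  if (misprime_fraction < 0 || misprime_fraction > 1)
    stop("misprime_fraction must be in [0, 1]")
  set.seed(seed)
  gi <- sample.int(nrow(annotation), n_reads, replace = TRUE)
  # keep 3' ends >6 bp from chromosome ends so mispriming is always resolvable
  pos <- annotation$start[gi] +
    floor(runif(n_reads) * (annotation$end[gi] - annotation$start[gi]))
  tstrand <- annotation$strand[gi]
  astrand <- ifelse(tstrand == "+", "-", "+")
  # 5' end of the aligned read sits at the recorded 3'-end position
  start <- ifelse(astrand == "+", pos, pmax(0L, pos + 1L - read_length))
  end <- ifelse(astrand == "+",
                pmin(pos + read_length,
                     Biostrings::width(genome)[match(annotation$chrom[gi], names(genome))]),
                pos + 1L)
  mis <- runif(n_reads) < misprime_fraction
  barcode <- vapply(seq_len(n_reads), function(i)
    paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = ""),
    character(1))
  if (any(mis)) {
    hx <- adjacent_hexamer(genome, annotation$chrom[gi][mis], pos[mis], tstrand[mis])
    barcode[mis][!is.na(hx)] <- hx[!is.na(hx)]
  }
  out <- data.frame(chrom = annotation$chrom[gi], start = start, end = end,
                    alignment_strand = astrand, barcode = barcode,
                    stringsAsFactors = FALSE)
  class(out) <- c("read_records", "data.frame")
  out
}

#' Write a full synthetic dataset to disk
#'
#' Writes the genome (FASTA), annotation (GFF3), both replicate tracks
#' (strand-split bedGraph), the pause truth table (TSV) and the configuration
#' echo (JSON) under a directory.
#'
#' @param sim Output of [simulate_occupancy()].
#' @param genome,annotation From [generate_toy_genome()].
#' @param config The [simulation_config()] used.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, genome, annotation, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
  write_annotation_gff3(annotation, file.path(dir, "annotation.gff3"))
  write_track_bedgraph(sim$rep1, file.path(dir, "rep1"))
  write_track_bedgraph(sim$rep2, file.path(dir, "rep2"))
  write.table(sim$truth, file.path(dir, "pause_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
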