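#' Count-matched shuffled control loci
#'
#' For each host gene, draws as many uniform random non-pause positions as
#' the gene has real pauses (controlling for differential gene expression, as
#' the per-gene locus counts are identical). Controls never coincide with a
#' real pause; a gene saturated by pauses is an error.
#'
#' @param pauses a `pause_calls` data frame.
#' @param annotation A [tx_annotation()].
#' @param seed integer seed.
#' @return Data frame like `pauses` with `label = "control"`; the input loci
#'   are returned alongside under `label = "real"` by [assemble_features()].
#' @export
shuffled_control_loci <- function(pauses, annotation, seed = 1) {
  set.seed(seed)
  out <- pauses
  for (g in unique(pauses$gene_id)) {
    i <- which(pauses$gene_id == g)
    a <- annotation[annotation$gene_id == g, ]
    if (nrow(a) != 1) stop("gene ", g, " absent from annotation")
    len <- a$end - a$start
    taken <- pauses$pos[i] - a$start + 1L
    avail <- setdiff(seq_len(len), taken)
    if (length(avail) < length(i))
      stop("gene ", g, " is saturated by pauses; no control positions left")
    out$pos[i] <- a$start + sample(avail, length(i)) - 1L
  }
  out$label <- "control"
  out
}

# SantaLucia unified nearest-neighbor parameters (kcal/mol, cal/mol/K)
.nn_dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
            GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
.nn_ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -24.4)

# canonicalize a dinucleotide step to the 10 unique NN keys
.nn_key <- function(steps) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  alt <- vapply(strsplit(steps, ""), function(b)
    paste0(comp[b[2]], comp[b[1]]), character(1))
  ifelse(steps %in% names(.nn_dh), steps, alt)
}

#' Nearest-neighbor duplex melting temperature
#'
#' SantaLucia unified nearest-neighbor thermodynamics at 50 nM strand
#' concentration, reported in degrees Celsius. Sequences with non-ACGT
#' characters return `NA`.
#'
#' @param seqs character vector of DNA sequences (>= 2 nt).
#' @return Numeric vector of melting temperatures.
#' @export
melting_temperature <- function(seqs) {
  vapply(seqs, function(s) {
    if (is.na(s) || grepl("[^ACGT]", s) || nchar(s) < 2) return(NA_real_)
    b <- strsplit(s, "")[[1]]
    steps <- .nn_key(paste0(b[-length(b)], b[-1]))
    dh <- sum(.nn_dh[steps]) * 1000  # cal/mol
    ds <- sum(.nn_ds[steps])
    # initiation terms (terminal G/C vs A/T)
    for (term in c(b[1], b[length(b)])) {
      if (term %in% c("G", "C")) { dh <- dh + 100; ds <- ds + (-2.8) }
      else { dh <- dh + 2300; ds <- ds + 4.1 }
    }
    dh / (ds + 1.987 * log(5e-8 / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a pentamer DNA-shape lookup table
#'
#' TSV with columns `pentamer`, `twist`, `roll`, `propeller`, `mgw` (one row
#' per 5-mer).
#'
#' @param path TSV path.
#' @return Data frame keyed by pentamer.
#' @export
read_shape_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("pentamer", "twist", "roll", "propeller", "mgw")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("shape table missing columns: ", paste(miss, collapse = ", "))
  tab
}

#' Synthetic pentamer shape table
#'
#' A deterministic stand-in for a published pentamer DNA-shape lookup table,
#' for demonstrations and tests: each shape value is a smooth function of the
#' pentamer's AT content and central dinucleotide, loosely centered on
#' helical-parameter scales (twist near 34 degrees, AT-rich steps lower).
#' This is synthetic data, not measured shape.
#'
#' @param constant optional single value; when given, every entry of every
#'   shape column is set to it (useful for lookup-identity tests).
#' @return Data frame in [read_shape_table()] layout covering all 1024
#'   pentamers.
#' @export
synthetic_shape_table <- function(constant = NULL) {
  bases <- c("A", "C", "G", "T")
  pent <- do.call(paste0, expand.grid(bases, bases, bases, bases, bases,
                                      stringsAsFactors = FALSE)[, 5:1])
  at <- vapply(strsplit(pent, ""), function(b) mean(b %in% c("A", "T")),
               numeric(1))
  if (!is.null(constant)) {
    return(data.frame(pentamer = pent, twist = constant, roll = constant,
                      propeller = constant, mgw = constant,
                      stringsAsFactors = FALSE))
  }
  data.frame(pentamer = pent,
             twist = 34.5 - 2.4 * at,
             roll = 0.6 + 4.0 * (at - 0.5),
             propeller = -6.0 - 8.0 * at,
             mgw = 5.8 - 1.5 * at,
             stringsAsFactors = FALSE)
}

# strand-aware sequence around loci: 2*flank+1 nt centered on the locus, in
# transcript orientation; NA when the window runs off the chromosome
locus_sequences <- function(loci, genome, flank) {
  n <- nrow(loci)
  out <- rep(NA_character_, n)
  len <- Biostrings::width(genome)[match(loci$chrom, names(genome))]
  ok <- loci$pos - flank >= 0 & loci$pos + flank < len
  if (any(ok)) {
    seqs <- Biostrings::subseq(genome[loci$chrom[ok]],
                               start = loci$pos[ok] - flank + 1L,
                               width = 2L * flank + 1L)
    minus <- loci$strand[ok] == "-"
    if (any(minus)) seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
    out[ok] <- as.character(seqs)
  }
  out
}

#' Assemble per-locus feature vectors
#'
#' Builds the feature table for real pause loci and their count-matched
#' controls: the centered trinucleotide, per-offset base identities over
#' +/- `seq_window` nt (strand-aware, reverse-complemented on the minus
#' strand), nearest-neighbor melting temperature and GC fraction of the
#' window, DNA-shape values of the centered pentamer from a lookup table,
#' mean signal of arbitrary genomic tracks in +/- `track_window`, and
#' positional features (relative position in gene, distances to TSS and
#' poly(A)). Loci within `seq_window` of a chromosome end keep their row with
#' sequence features set to missing and `edge_flag = TRUE`.
#'
#' @param real a `pause_calls` data frame (the real loci).
#' @param control matched control loci from [shuffled_control_loci()].
#' @param genome A [Biostrings::DNAStringSet].
#' @param annotation A [tx_annotation()].
#' @param tracks named list of [occupancy_track()]s used as signal features
#'   (mean in the window, strand-matched).
#' @param shape_table optional data frame from [read_shape_table()] /
#'   [synthetic_shape_table()].
#' @param seq_window half-width for sequence features (default 10).
#' @param track_window half-width for track features (default 25).
#' @return Data frame with `label` (`"real"`/`"control"`), `gene_id`, feature
#'   columns, and `edge_flag`.
#' @export
assemble_features <- function(real, control, genome, annotation,
                              tracks = list(), shape_table = NULL,
                              seq_window = 10, track_window = 25) {
  real$label <- "real"
  control$label <- "control"
  common <- intersect(names(real), names(control))
  loci <- rbind(as.data.frame(real)[, common], as.data.frame(control)[, common])
  seqs <- locus_sequences(loci, genome, seq_window)
  center <- seq_window + 1L
  out <- data.frame(label = loci$label, gene_id = loci$gene_id,
                    chrom = loci$chrom, pos = loci$pos, strand = loci$strand,
                    stringsAsFactors = FALSE)
  out$edge_flag <- is.na(seqs)
  out$trinuc <- factor(substr(seqs, center - 1L, center + 1L))
  for (k in seq.int(-seq_window, seq_window)) {
    nm <- sprintf("base_%s%d", ifelse(k < 0, "m", "p"), abs(k))
    out[[nm]] <- factor(substr(seqs, center + k, center + k),
                        levels = c("A", "C", "G", "T"))
  }
  out$tm <- melting_temperature(seqs)
  out$gc_window <- vapply(seqs, function(s) {
    if (is.na(s)) return(NA_real_)
    mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
  if (!is.null(shape_table)) {
    pent <- substr(seqs, center - 2L, center + 2L)
    idx <- match(pent, shape_table$pentamer)
    for (col in c("twist", "roll", "propeller", "mgw"))
      out[[col]] <- shape_table[[col]][idx]
  }
  for (tn in names(tracks)) {
    out[[paste0("track_", tn)]] <- vapply(seq_len(nrow(loci)), function(i) {
      p <- seq.int(loci$pos[i] - track_window, loci$pos[i] + track_window)
      mean(positions_signal(tracks[[tn]], loci$chrom[i], p[p >= 0],
                            loci$strand[i]))
    }, numeric(1))
  }
  ai <- match(loci$gene_id, annotation$gene_id)
  len <- tx_length(annotation)[ai]
  off <- ifelse(annotation$strand[ai] == "+",
                loci$pos - annotation$start[ai],
                annotation$end[ai] - 1L - loci$pos)
  out$rel_pos <- off / len
  out$dist_tss <- off
  out$dist_polya <- len - 1L - off
  rownames(out) <- NULL
  out
}

#' Test feature distributions, real versus control
#'
#' Two-sample Student's t-test per numeric feature with Bonferroni correction
#' over the tested features. Categorical (sequence) features are skipped with
#' a note; zero-variance features are skipped and flagged.
#'
#' @param table feature table from [assemble_features()].
#' @return Data frame: `feature`, `statistic`, `p`, `p_adjusted`
#'   (Bonferroni), `skipped`, `note`.
#' @export
feature_distribution_tests <- function(table) {
  meta <- c("label", "gene_id", "chrom", "pos", "strand", "edge_flag")
  feats <- setdiff(names(table), meta)
  rows <- lapply(feats, function(f) {
    x <- table[[f]]
    if (!is.numeric(x))
      return(data.frame(feature = f, statistic = NA_real_, p = NA_real_,
                        skipped = TRUE, note = "categorical",
                        stringsAsFactors = FALSE))
    a <- x[table$label == "real"]; b <- x[table$label == "control"]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2 || (var(a) == 0 && var(b) == 0))
      return(data.frame(feature = f, statistic = NA_real_, p = NA_real_,
                        skipped = TRUE, note = "zero variance",
                        stringsAsFactors = FALSE))
    tt <- t.test(a, b)
    data.frame(feature = f, statistic = unname(tt$statistic), p = tt$p.value,
               skipped = FALSE, note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tested <- !out$skipped
  if (sum(tested) < 2) stop("need at least 2 testable numeric features")
  out$p_adjusted <- NA_real_
  out$p_adjusted[tested] <- p.adjust(out$p[tested], method = "bonferroni")
  out
}

#' Export pause-flank sequences as FASTA
#'
#' Writes the +/- `flank` nt sequence around each locus (strand-aware) for
#' external motif tools.
#'
#' @param loci a `pause_calls`-style data frame.
#' @param genome A [Biostrings::DNAStringSet].
#' @param path output FASTA path.
#' @param flank half-width (default 10).
#' @return `path`, invisibly.
#' @export
export_pause_flank_fasta <- function(loci, genome, path, flank = 10) {
  seqs <- locus_sequences(loci, genome, flank)
  ok <- !is.na(seqs)
  ss <- Biostrings::DNAStringSet(seqs[ok])
  names(ss) <- paste(loci$chrom[ok], loci$pos[ok], loci$strand[ok], sep = ":")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
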