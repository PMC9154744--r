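#' Pause density
#'
#' Pauses per kb of the genome considered when extracting pause positions:
#' the combined length of all well-expressed genes in both replicates.
#'
#' @param pauses a `pause_calls` data frame.
#' @param considered_length total bp over which pauses were callable.
#' @return Pauses per kb.
#' @export
pause_density <- function(pauses, considered_length) {
  if (considered_length <= 0) stop("considered_length must be positive")
  1000 * nrow(pauses) / considered_length
}

# strand-aware relative position of a pause in its host gene, in [0, 1)
relative_positions <- function(pauses, annotation) {
  idx <- match(pauses$gene_id, annotation$gene_id)
  if (anyNA(idx)) stop("pause assigned to a gene absent from the annotation")
  len <- tx_length(annotation)[idx]
  off <- ifelse(annotation$strand[idx] == "+",
                pauses$pos - annotation$start[idx],
                annotation$end[idx] - 1L - pauses$pos)
  if (any(off < 0 | off >= len)) stop("pause outside its host gene")
  off / len
}

#' Positional distribution of pauses across gene bodies
#'
#' Genes are length-normalized; the 5' region is the first 15% of the gene,
#' the 3' region the last 15% (ending at the poly(A) site) and the mid region
#' spans the 15th to 85th percentile. Fractions are averaged across genes
#' with a normal-approximation 95% confidence interval.
#'
#' @param pauses a `pause_calls` data frame.
#' @param annotation A [tx_annotation()].
#' @return Data frame with one row per bin (`five_prime`, `mid`,
#'   `three_prime`): mean fraction across genes, `lo`/`hi` 95% CI, and the
#'   pooled fraction over all pauses.
#' @export
positional_distribution <- function(pauses, annotation) {
  rel <- relative_positions(pauses, annotation)
  bin <- cut(rel, breaks = c(-Inf, 0.15, 0.85, Inf),
             labels = c("five_prime", "mid", "three_prime"))
  per_gene <- table(pauses$gene_id)
  genes <- names(per_gene)
  fr <- t(vapply(genes, function(g) {
    b <- bin[pauses$gene_id == g]
    as.numeric(table(b) / length(b))
  }, numeric(3)))
  colnames(fr) <- c("five_prime", "mid", "three_prime")
  m <- colMeans(fr)
  se <- apply(fr, 2, sd) / sqrt(nrow(fr))
  data.frame(bin = colnames(fr), mean = m, lo = m - 1.96 * se,
             hi = m + 1.96 * se,
             pooled = as.numeric(table(bin) / length(bin)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Scramble pauses uniformly within their host genes
#'
#' The positional null control: each pause is replaced by a uniform random
#' position within its host gene (same strand), preserving per-gene pause
#' counts exactly; duplicate positions are resolved by resampling.
#'
#' @param pauses a `pause_calls` data frame.
#' @param annotation A [tx_annotation()].
#' @param seed integer seed.
#' @return A `pause_calls` data frame of scrambled loci (reads carried over).
#' @export
scramble_pauses <- function(pauses, annotation, seed = 1) {
  set.seed(seed)
  out <- pauses
  for (g in unique(pauses$gene_id)) {
    i <- which(pauses$gene_id == g)
    a <- annotation[annotation$gene_id == g, ]
    if (nrow(a) != 1) stop("gene ", g, " absent from annotation")
    len <- a$end - a$start
    if (length(i) > len) stop("gene ", g, " has more pauses than positions")
    out$pos[i] <- a$start + sample.int(len, length(i)) - 1L
  }
  class(out) <- c("pause_calls", "data.frame")
  out
}

#' Cross-strain shared-pause matrix
#'
#' Tri-state matrix over pause loci found in at least `min_strains` strains:
#' `"pause"` where the strain called the locus, `"insufficient-coverage"`
#' where the locus's host gene failed that strain's expression filter (the
#' coverage proxy), `"no-pause"` otherwise. Missing states are stored
#' explicitly, never imputed.
#'
#' @param pause_sets named list of `pause_calls` data frames, one per strain.
#' @param expressed_sets named list (same names) of character vectors of
#'   well-expressed gene ids per strain.
#' @param annotation A [tx_annotation()] (to find each locus's host gene).
#' @param min_strains minimum strains sharing a locus (default 8).
#' @return Character matrix, rows = `chrom:pos:strand` loci, columns =
#'   strains.
#' @export
shared_pause_matrix <- function(pause_sets, expressed_sets, annotation,
                                min_strains = 8) {
  stopifnot(identical(sort(names(pause_sets)), sort(names(expressed_sets))))
  strains <- names(pause_sets)
  all_calls <- data.table::rbindlist(lapply(strains, function(s) {
    d <- pause_sets[[s]]
    data.table::data.table(locus = paste(d$chrom, d$pos, d$strand, sep = ":"),
                           gene_id = d$gene_id, strain = s)
  }))
  tab <- all_calls[, list(n = length(unique(strain))), by = c("locus", "gene_id")]
  keep <- tab[tab$n >= min_strains]
  if (!nrow(keep))
    return(matrix(character(0), nrow = 0, ncol = length(strains),
                  dimnames = list(NULL, strains)))
  m <- matrix("no-pause", nrow = nrow(keep), ncol = length(strains),
              dimnames = list(keep$locus, strains))
  for (s in strains) {
    covered <- keep$gene_id %in% expressed_sets[[s]]
    called <- keep$locus %in% all_calls[all_calls$strain == s]$locus
    m[called, s] <- "pause"
    m[!covered, s] <- "insufficient-coverage"  # wins regardless of reads
  }
  m
}
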