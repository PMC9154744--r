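#' Build antisense transcription-unit annotation
#'
#' One antisense unit per protein-coding gene: identical coordinates, opposite
#' strand, id `"anti" + gene_id`. Units that overlap (any bp) a known sense
#' transcription unit on their own strand are removed.
#'
#' @param annotation A [tx_annotation()] of sense units.
#' @return A [tx_annotation()] of the retained antisense units, with attribute
#'   `"removed"` listing the dropped ids.
#' @export
build_antisense_annotation <- function(annotation) {
  sense <- annotation[annotation$type == "gene", , drop = FALSE]
  anti <- sense
  anti$gene_id <- paste0("anti", sense$gene_id)
  anti$strand <- ifelse(sense$strand == "+", "-", "+")
  anti$tss <- ifelse(anti$strand == "+", anti$start, anti$end - 1L)
  anti$polya <- ifelse(anti$strand == "+", anti$end - 1L, anti$start)
  anti$intron_start <- NA_integer_
  anti$intron_end <- NA_integer_
  anti$type <- "antisense"
  # drop units overlapping a sense unit on the antisense unit's own strand
  gr_anti <- GenomicRanges::GRanges(anti$chrom,
                                    IRanges::IRanges(anti$start + 1L, anti$end),
                                    strand = anti$strand)
  gr_sense <- GenomicRanges::GRanges(sense$chrom,
                                     IRanges::IRanges(sense$start + 1L, sense$end),
                                     strand = sense$strand)
  hits <- GenomicRanges::findOverlaps(gr_anti, gr_sense, ignore.strand = FALSE)
  drop <- unique(S4Vectors::queryHits(hits))
  removed <- anti$gene_id[drop]
  out <- if (length(drop)) anti[-drop, , drop = FALSE] else anti
  rownames(out) <- NULL
  out <- tx_annotation(out)
  attr(out, "removed") <- removed
  out
}

#' Positional antisense log2-RPKM matrix
#'
#' Rows are genes, columns offsets from `window[1]` (default -250) upstream
#' of the sense TSS to `window[2]` (default +4000) downstream, in sense
#' orientation. Values are log2(RPKM + 1) of the antisense-strand signal; a
#' pseudocount of 1 is added to every position before the log. Positions
#' downstream of the gene's poly(A) site are missing (`NA`) for genes shorter
#' than the window. Per-position RPKM from a per-million track is the
#' per-million count x 1000 (one bp = 1/1000 kb).
#'
#' @param track a per-million normalized [occupancy_track()].
#' @param annotation A [tx_annotation()] of sense genes.
#' @param window offset pair relative to the sense TSS.
#' @return Numeric matrix (genes x offsets) with dimnames.
#' @export
antisense_log_matrix <- function(track, annotation, window = c(-250, 4000)) {
  if (!track$normalized)
    stop("antisense_log_matrix expects a per-million normalized track")
  off <- seq.int(window[1], window[2])
  mat <- matrix(NA_real_, nrow(annotation), length(off),
                dimnames = list(annotation$gene_id, off))
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    astrand <- if (a$strand == "+") "-" else "+"
    gpos <- window_positions(a$tss, a$strand, window)
    # keep offsets up to the gene 3' end; pad the rest with NA
    in_range <- if (a$strand == "+") gpos < a$end else gpos >= a$start
    in_range <- in_range & gpos >= 0
    vals <- positions_signal(track, a$chrom, gpos[in_range], astrand)
    mat[i, in_range] <- log2(vals * 1000 + 1)
  }
  mat
}

#' Write / read a position matrix as TSV
#'
#' Values are written at full double precision (`%.17g`), so a write/read
#' round trip is bit-identical.
#'
#' @param m matrix from [antisense_log_matrix()] or [differential_matrix()].
#' @param path TSV path.
#' @return `path` invisibly; `read_position_matrix()` returns the matrix.
#' @export
write_position_matrix <- function(m, path) {
  txt <- apply(m, 1, function(row)
    paste(ifelse(is.na(row), "NA", sprintf("%.17g", row)), collapse = "\t"))
  writeLines(c(paste(c("gene_id", colnames(m)), collapse = "\t"),
               paste(rownames(m), txt, sep = "\t")), path)
  invisible(path)
}

#' @rdname write_position_matrix
#' @export
read_position_matrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    row.names = 1)
  as.matrix(tab)
}

#' Differential antisense matrix
#'
#' Element-wise difference of two pseudocounted log2 matrices, i.e.
#' log2((mutant + 1) / (wild-type + 1)) per position. Missing stays missing.
#'
#' @param matrix_mutant,matrix_wt matrices from [antisense_log_matrix()] with
#'   identical row sets.
#' @return Matrix of log2 ratios.
#' @export
differential_matrix <- function(matrix_mutant, matrix_wt) {
  if (!identical(rownames(matrix_mutant), rownames(matrix_wt)) ||
      !identical(dim(matrix_mutant), dim(matrix_wt)))
    stop("mutant and wild-type matrices have mismatched rows")
  matrix_mutant - matrix_wt
}

#' Sense-antisense fold-change correlation
#'
#' Pearson r between per-gene sense and antisense log2 fold changes, per
#' strain and pooled over all strain-gene pairs.
#'
#' @param fold_changes list (one element per strain) of data frames with
#'   `gene_id`, `sense`, `antisense` log2 fold-change columns.
#' @return Data frame with one row per strain plus a `"pooled"` row: `strain`,
#'   `r`, `n`.
#' @export
sense_antisense_correlation <- function(fold_changes) {
  if (is.data.frame(fold_changes)) fold_changes <- list(strain = fold_changes)
  rows <- lapply(names(fold_changes), function(s) {
    d <- fold_changes[[s]]
    d <- d[is.finite(d$sense) & is.finite(d$antisense), , drop = FALSE]
    if (nrow(d) < 3) stop("fewer than 3 matched sense/antisense pairs for ", s)
    data.frame(strain = s, r = cor(d$sense, d$antisense), n = nrow(d),
               stringsAsFactors = FALSE)
  })
  pooled <- do.call(rbind, lapply(fold_changes, function(d)
    d[is.finite(d$sense) & is.finite(d$antisense), c("sense", "antisense")]))
  rbind(do.call(rbind, rows),
        data.frame(strain = "pooled", r = cor(pooled$sense, pooled$antisense),
                   n = nrow(pooled), stringsAsFactors = FALSE))
}
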