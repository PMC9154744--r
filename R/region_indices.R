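#' Default region windows for pausing indices
#'
#' Strand-aware offsets relative to the anchor, inclusive at both ends:
#' TSS (-50, +150), poly(A) (-100, +100), 5'/3' splice sites (-10, +10).
#' Negative offsets are upstream of the anchor in transcript orientation.
#'
#' @return Named list of `c(upstream, downstream)` offset pairs.
#' @export
default_region_windows <- function() {
  list(tss = c(-50, 150), polya = c(-100, 100), ss5 = c(-10, 10),
       ss3 = c(-10, 10), antisense = c(-50, 150))
}

# anchor genomic position (0-based) per gene for a region type; NA when the
# gene lacks the anchor (e.g. no intron)
region_anchor <- function(ann, region) {
  switch(region,
    tss = ann$tss,
    polya = ann$polya,
    ss5 = splice_sites(ann)$ss5,
    ss3 = splice_sites(ann)$ss3,
    stop("unknown region: ", region))
}

# genomic positions of offsets [w1, w2] around an anchor, transcript-strand
# aware (offset +1 is one bp downstream in transcript orientation)
window_positions <- function(anchor, strand, w) {
  off <- seq.int(w[1], w[2])
  if (strand == "+") anchor + off else anchor - off
}

#' Per-gene pausing index for a region
#'
#' PI = (region reads / region length) / (remainder reads / remainder
#' length). The remainder is every gene-body position not inside the region;
#' region positions falling outside the annotated gene (e.g. upstream of the
#' TSS) count in the numerator only. PI is scale-invariant, so raw or
#' normalized merged tracks give identical values.
#'
#' @param track an [occupancy_track()].
#' @param annotation A [tx_annotation()].
#' @param region one of `"tss"`, `"polya"`, `"ss5"`, `"ss3"`.
#' @param windows window list as from [default_region_windows()].
#' @return Data frame: `gene_id`, `region`, `region_density`, `body_density`,
#'   `pi`, `defined`. PI is `NA` with `defined = FALSE` when the remainder
#'   density is 0; genes shorter than the window, or lacking the anchor, are
#'   skipped.
#' @export
pausing_index <- function(track, annotation, region = "tss",
                          windows = default_region_windows()) {
  w <- windows[[region]]
  if (is.null(w)) stop("no window for region ", region)
  anchors <- region_anchor(annotation, region)
  rows <- vector("list", nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    if (is.na(anchors[i])) next
    len <- a$end - a$start
    if (len <= w[2] - w[1] + 1) next  # remainder would be empty
    rpos <- window_positions(anchors[i], a$strand, w)
    rpos <- rpos[rpos >= 0]
    region_reads <- sum(positions_signal(track, a$chrom, rpos, a$strand))
    in_gene <- rpos >= a$start & rpos < a$end
    body_pos <- setdiff(seq.int(a$start, a$end - 1L), rpos[in_gene])
    if (!length(body_pos)) next
    body_reads <- sum(positions_signal(track, a$chrom, body_pos, a$strand))
    rd <- region_reads / length(rpos)
    bd <- body_reads / length(body_pos)
    rows[[i]] <- data.frame(gene_id = a$gene_id, region = region,
                            region_density = rd, body_density = bd,
                            pi = if (bd > 0) rd / bd else NA_real_,
                            defined = bd > 0, stringsAsFactors = FALSE)
  }
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), region = character(),
               region_density = numeric(), body_density = numeric(),
               pi = numeric(), defined = logical())
  rownames(out) <- NULL
  out
}

#' Antisense pausing index
#'
#' PI on the antisense strand with the TSS-style window anchored at the
#' antisense-unit start (opposite the host gene's poly(A) region), the body
#' being the antisense unit itself.
#'
#' @param track an [occupancy_track()].
#' @param antisense_annotation antisense units from
#'   [build_antisense_annotation()].
#' @param windows window list; the `antisense` entry is used.
#' @return As [pausing_index()], with `region = "antisense"`.
#' @export
antisense_pausing_index <- function(track, antisense_annotation,
                                    windows = default_region_windows()) {
  out <- pausing_index(track, antisense_annotation, region = "tss",
                       windows = list(tss = windows$antisense))
  if (nrow(out)) out$region <- "antisense"
  out
}

#' Metagene profile around an anchor
#'
#' Per-gene signal over a fixed offset window around the anchor (strand
#' aware), normalized per gene (sum-to-1 by default), then averaged across
#' genes with a 95% CI from the per-gene variation and smoothed with local
#' regression (loess, default span 0.01, degree 1).
#'
#' @param track an [occupancy_track()].
#' @param annotation A [tx_annotation()]; restrict to non-overlapping
#'   protein-coding genes upstream of this call.
#' @param anchor `"tss"`, `"polya"`, `"ss5"` or `"ss3"`.
#' @param window offset pair, defaults: TSS (-100, +600), poly(A)
#'   (-500, +200), splice sites (-25, +25).
#' @param norm per-gene normalization, `"sum"` or `"max"`.
#' @param span loess span (default 0.01; the effective span is widened so at
#'   least 4 points support each local fit).
#' @return Data frame: `offset`, `mean`, `lo`, `hi`, `smoothed`.
#' @export
metagene_profile <- function(track, annotation, anchor = "tss",
                             window = NULL, norm = c("sum", "max"),
                             span = 0.01) {
  norm <- match.arg(norm)
  if (is.null(window))
    window <- switch(anchor, tss = c(-100, 600), polya = c(-500, 200),
                     ss5 = c(-25, 25), ss3 = c(-25, 25),
                     stop("unknown anchor: ", anchor))
  anchors <- region_anchor(annotation, anchor)
  keep <- !is.na(anchors)
  mat <- t(vapply(which(keep), function(i) {
    a <- annotation[i, ]
    positions_signal(track, a$chrom,
                     window_positions(anchors[i], a$strand, window), a$strand)
  }, numeric(window[2] - window[1] + 1)))
  tot <- if (norm == "sum") rowSums(mat) else apply(mat, 1, max)
  mat <- mat[tot > 0, , drop = FALSE] / tot[tot > 0]
  if (nrow(mat) < 10) stop("fewer than 10 contributing genes for metagene")
  off <- seq.int(window[1], window[2])
  m <- colMeans(mat)
  se <- apply(mat, 2, sd) / sqrt(nrow(mat))
  eff_span <- max(span, 4 / length(off))
  sm <- tryCatch(
    predict(loess(m ~ off, span = eff_span, degree = 1)),
    error = function(e) m)
  data.frame(offset = off, mean = m, lo = m - 1.96 * se, hi = m + 1.96 * se,
             smoothed = sm)
}

#' Splicing index per intron
#'
#' SI = 2 * spliced / (unspliced5 + unspliced3), from junction-spanning read
#' counts (computed upstream with the >= 3 nt overhang rule). The index is
#' undefined when no unspliced reads are observed.
#'
#' @param junctions data frame with `intron_id`, `spliced`, `unspliced5`,
#'   `unspliced3` (see [simulate_junction_counts()]).
#' @return The junction table with an `si` column (`NA` when undefined).
#' @export
splicing_index <- function(junctions) {
  denom <- junctions$unspliced5 + junctions$unspliced3
  junctions$si <- ifelse(denom > 0, 2 * junctions$spliced / denom, NA_real_)
  junctions
}

#' Paired comparison of splicing indices between two samples
#'
#' Wilcoxon signed-rank test across introns defined (finite SI) in both
#' samples; introns with an undefined index in either sample are excluded and
#' tallied.
#'
#' @param junctions_a,junctions_b junction tables for the two samples.
#' @return List with `test` (the `htest`), `n_used`, `n_excluded`,
#'   `median_a`, `median_b`.
#' @export
compare_splicing <- function(junctions_a, junctions_b) {
  a <- splicing_index(junctions_a)
  b <- splicing_index(junctions_b)
  m <- merge(a[, c("intron_id", "si")], b[, c("intron_id", "si")],
             by = "intron_id", suffixes = c("_a", "_b"))
  ok <- is.finite(m$si_a) & is.finite(m$si_b)
  if (sum(ok) < 3) stop("too few introns with defined splicing index in both samples")
  tt <- wilcox.test(m$si_a[ok], m$si_b[ok], paired = TRUE, exact = FALSE)
  list(test = tt, n_used = sum(ok), n_excluded = sum(!ok),
       median_a = stats::median(m$si_a[ok]), median_b = stats::median(m$si_b[ok]))
}
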