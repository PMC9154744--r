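#' Select well-expressed genes
#'
#' Only genes with average coverage strictly above `min_coverage` reads per
#' base pair in both replicates are eligible for pause calling.
#'
#' @param track_rep1,track_rep2 raw [occupancy_track()]s for the two
#'   replicates.
#' @param annotation A [tx_annotation()].
#' @param min_coverage threshold in reads/bp (default 2; the comparison is
#'   strict, so a mean of exactly 2.0 fails).
#' @return Data frame with `gene_id`, `mean_rep1`, `mean_rep2`, `passes`.
#' @export
select_well_expressed <- function(track_rep1, track_rep2, annotation,
                                  min_coverage = 2) {
  if (track_rep1$normalized || track_rep2$normalized)
    stop("expression filter expects raw tracks")
  len <- tx_length(annotation)
  m1 <- unit_sums(track_rep1, annotation) / len
  m2 <- unit_sums(track_rep2, annotation) / len
  data.frame(gene_id = annotation$gene_id, mean_rep1 = m1, mean_rep2 = m2,
             passes = m1 > min_coverage & m2 > min_coverage,
             stringsAsFactors = FALSE)
}

#' Fit a negative-binomial background to a window of counts
#'
#' Method-of-moments fit: mu is the sample mean and the standard deviation is
#' the sample standard deviation; the NB size parameter is
#' r = mu^2 / (var - mu). When the sample variance does not exceed the mean
#' the fit falls back to Poisson (sd = sqrt(mu)). An all-zero window returns
#' mu = sd = 0, so the call threshold degenerates to the minimum-read floor.
#'
#' @param counts numeric vector of counts over the non-pause positions of the
#'   window (at most 200).
#' @return List of class `background_fit` with `mu`, `sd`, `distribution`
#'   (`"NB"` or `"Poisson"`), `nb_size`, `n`.
#' @export
fit_background <- function(counts) {
  n <- length(counts)
  mu <- if (n) mean(counts) else 0
  if (n < 2 || mu == 0) {
    fit <- list(mu = mu, sd = if (mu > 0) sqrt(mu) else 0,
                distribution = "Poisson", nb_size = Inf, n = n)
  } else {
    v <- var(counts)
    if (v > mu) {
      fit <- list(mu = mu, sd = sqrt(v), distribution = "NB",
                  nb_size = mu^2 / (v - mu), n = n)
    } else {
      fit <- list(mu = mu, sd = sqrt(mu), distribution = "Poisson",
                  nb_size = Inf, n = n)
    }
  }
  class(fit) <- "background_fit"
  fit
}

# Vectorized per-position background moments for one gene: for each position
# i, mean/sd over the window of +/- half non-pause positions, excluding i
# itself. Running sums over pause-masked counts give O(N) per sweep.
window_moments <- function(x, mask, half) {
  n <- length(x)
  keep <- as.numeric(!mask)
  xk <- x * keep
  c0 <- cumsum(keep); c1 <- cumsum(xk); c2 <- cumsum(xk * x)
  lo <- pmax(seq_len(n) - half, 1L); hi <- pmin(seq_len(n) + half, n)
  wsum0 <- c0[hi] - c0[lo] + keep[lo]
  wsum1 <- c1[hi] - c1[lo] + xk[lo]
  wsum2 <- c2[hi] - c2[lo] + (xk * x)[lo]
  # exclude the candidate position itself
  m <- wsum0 - keep
  s1 <- wsum1 - xk
  s2 <- wsum2 - xk * x
  mu <- ifelse(m > 0, s1 / m, 0)
  vv <- ifelse(m > 1, (s2 - m * mu^2) / (m - 1), 0)
  vv[vv < 0] <- 0  # guard tiny negatives from float cancellation
  list(n = m, mu = mu, var = vv)
}

# threshold per position given moments: mu + 3 sd with NB/Poisson branch
threshold_from_moments <- function(mu, vv, z) {
  sdv <- ifelse(vv > mu, sqrt(vv), sqrt(mu))
  mu + z * sdv
}

#' Call single-nucleotide pause sites in one replicate
#'
#' For each position of each well-expressed gene, the surrounding `window`
#' nucleotides (half on each side, truncated at gene boundaries, candidate
#' excluded) that do not contain pauses are fit with the method-of-moments
#' negative-binomial background of [fit_background()]; a position is a pause
#' iff its reads exceed mean + `z` standard deviations and meet the
#' `min_reads` floor. Because the background must exclude pauses, calling is
#' iterated (call, refit excluding calls, repeat) to a fixed point, with a cap
#' of `max_iter` sweeps; genes that do not converge are kept at the last
#' iterate and flagged.
#'
#' @param track raw [occupancy_track()] of one replicate.
#' @param annotation A [tx_annotation()].
#' @param filter result of [select_well_expressed()]; only passing genes are
#'   scanned.
#' @param z standard-deviation multiplier (default 3).
#' @param min_reads minimum reads at a pause (default 2).
#' @param window background window size in nt (default 200, i.e. +/-100).
#' @param min_informative minimum non-pause background positions required to
#'   fit (default 50); positions with fewer are not callable.
#' @param max_iter fixed-point iteration cap (default 10).
#' @return Data frame of class `pause_calls`: `chrom`, `pos` (0-based),
#'   `strand`, `gene_id`, `reads`, `z`. Non-converged genes are listed in
#'   attribute `"nonconverged"`.
#' @export
call_pauses <- function(track, annotation, filter, z = 3, min_reads = 2,
                        window = 200, min_informative = 50, max_iter = 10) {
  if (track$normalized) stop("pauses are called on raw tracks")
  half <- as.integer(window / 2)
  genes <- annotation[annotation$gene_id %in% filter$gene_id[filter$passes], ,
                      drop = FALSE]
  out <- vector("list", nrow(genes))
  nonconv <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    x <- gene_counts(track, g$chrom, g$start, g$end, g$strand)
    mask <- rep(FALSE, length(x))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      mo <- window_moments(x, mask, half)
      thr <- threshold_from_moments(mo$mu, mo$var, z)
      calls <- x > thr & x >= min_reads & mo$n >= min_informative
      if (identical(calls, mask)) { converged <- TRUE; break }
      mask <- calls
    }
    if (!converged) nonconv <- c(nonconv, g$gene_id)
    if (any(mask)) {
      off <- which(mask)  # 1-based offset from TSS in transcript orientation
      gpos <- if (g$strand == "+") g$start + off - 1L else g$end - off
      mo <- window_moments(x, mask, half)
      sdv <- ifelse(mo$var > mo$mu, sqrt(mo$var), sqrt(mo$mu))
      zval <- ifelse(sdv[off] > 0, (x[off] - mo$mu[off]) / sdv[off], Inf)
      out[[i]] <- data.frame(chrom = g$chrom, pos = gpos, strand = g$strand,
                             gene_id = g$gene_id, reads = x[off], z = zval,
                             stringsAsFactors = FALSE)
    }
  }
  out <- Filter(Negate(is.null), out)
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), strand = character(),
               gene_id = character(), reads = numeric(), z = numeric())
  rownames(res) <- NULL
  res <- res[order(res$chrom, res$strand, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("pause_calls", "data.frame")
  attr(res, "nonconverged") <- nonconv
  res
}

#' Write pause calls as BED6
#'
#' name = gene id, score = reads (pause strength).
#'
#' @param calls A `pause_calls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pauses_bed <- function(calls, path) {
  bed <- data.frame(calls$chrom, calls$pos, calls$pos + 1L, calls$gene_id,
                    calls$reads, calls$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
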