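#' Strand-specific single-nucleotide occupancy tracks
#'
#' An `occupancy_track` stores sparse per-position counts of nascent-RNA 3'
#' ends: a data table with columns `chrom`, `pos` (0-based), `strand`
#' (transcript strand, `"+"`/`"-"`) and `count`, plus the library size (total
#' retained reads) and a normalization flag. Raw tracks hold integer counts
#' summing to `library_size`; [normalize_per_million()] converts counts to
#' reads per million mapped reads.
#'
#' @param counts data frame with columns `chrom`, `pos`, `strand`, `count`.
#' @param library_size total retained reads; defaults to `sum(counts$count)`.
#' @param normalized logical flag.
#' @return An `occupancy_track` object.
#' @export
occupancy_track <- function(counts, library_size = NULL, normalized = FALSE) {
  ct <- data.table::as.data.table(counts)
  need <- c("chrom", "pos", "strand", "count")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stop("track counts missing columns: ", paste(miss, collapse = ", "))
  ct <- ct[, need, with = FALSE]
  if (nrow(ct) && any(ct$count < 0)) stop("negative counts in occupancy track")
  if (nrow(ct) && !all(ct$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ct <- ct[ct$count != 0]
  data.table::setkeyv(ct, c("chrom", "strand", "pos"))
  if (is.null(library_size)) library_size <- sum(ct$count)
  structure(list(counts = ct, library_size = library_size,
                 normalized = isTRUE(normalized)),
            class = "occupancy_track")
}

#' @export
print.occupancy_track <- function(x, ...) {
  cat(sprintf("<occupancy_track> %d nonzero positions, library_size = %s, %s\n",
              nrow(x$counts), format(x$library_size),
              if (x$normalized) "normalized (per million)" else "raw counts"))
  invisible(x)
}

#' Total signal in a track
#' @param track An [occupancy_track()].
#' @return Sum of all counts.
#' @export
track_total <- function(track) sum(track$counts$count)

# counts along one transcription unit, 5'->3' in transcript orientation;
# returns numeric vector of length end-start (position 1 = TSS)
gene_counts <- function(track, chrom, start, end, strand) {
  .c <- chrom; .s <- strand
  sub <- track$counts[list(.c, .s), nomatch = NULL]
  v <- numeric(end - start)
  sub <- sub[pos >= start & pos < end]
  if (nrow(sub)) v[sub$pos - start + 1L] <- sub$count
  if (strand == "-") v <- rev(v)
  v
}

# signal over arbitrary genomic positions (may fall outside any gene);
# positions are 0-based, vectorized, single chrom/strand
positions_signal <- function(track, chrom, positions, strand) {
  .c <- chrom; .s <- strand
  sub <- track$counts[list(.c, .s), nomatch = NULL]
  v <- numeric(length(positions))
  if (nrow(sub)) {
    idx <- match(positions, sub$pos)
    hit <- !is.na(idx)
    v[hit] <- sub$count[idx[hit]]
  }
  v
}

# strand-matched read sum over each unit of an annotation
unit_sums <- function(track, ann) {
  vapply(seq_len(nrow(ann)), function(i) {
    sub <- track$counts[list(ann$chrom[i], ann$strand[i]), nomatch = NULL]
    sum(sub$count[sub$pos >= ann$start[i] & sub$pos < ann$end[i]])
  }, numeric(1))
}

#' Write an occupancy track as strand-split bedGraph
#'
#' Writes `<prefix>.pos.bedgraph` and `<prefix>.neg.bedgraph` (0-based
#' half-open intervals, one line per run of equal signal).
#'
#' @param track An [occupancy_track()].
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_track_bedgraph <- function(track, prefix) {
  paths <- c(paste0(prefix, ".pos.bedgraph"), paste0(prefix, ".neg.bedgraph"))
  for (i in 1:2) {
    s <- c("+", "-")[i]
    sub <- track$counts[strand == s]
    gr <- GenomicRanges::GRanges(
      seqnames = sub$chrom,
      ranges = IRanges::IRanges(start = sub$pos + 1L, width = 1L),
      score = sub$count
    )
    rtracklayer::export(gr, paths[i], format = "bedGraph")
  }
  invisible(paths)
}

#' Read a strand-split bedGraph pair into an occupancy track
#'
#' @param prefix Path prefix used by [write_track_bedgraph()].
#' @param library_size Library size to attach; defaults to the track total.
#' @param normalized Whether the values are per-million normalized.
#' @return An [occupancy_track()].
#' @export
read_track_bedgraph <- function(prefix, library_size = NULL, normalized = FALSE) {
  parts <- lapply(1:2, function(i) {
    s <- c("+", "-")[i]
    path <- paste0(prefix, c(".pos.bedgraph", ".neg.bedgraph")[i])
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (!length(gr)) return(NULL)
    # expand runs back to single positions
    w <- GenomicRanges::width(gr)
    data.table::data.table(
      chrom = rep(as.character(GenomicRanges::seqnames(gr)), w),
      pos = unlist(lapply(seq_along(gr), function(j)
        seq.int(GenomicRanges::start(gr)[j] - 1L, length.out = w[j]))),
      strand = s,
      count = rep(gr$score, w)
    )
  })
  ct <- data.table::rbindlist(parts[!vapply(parts, is.null, logical(1))])
  if (!nrow(ct)) ct <- data.table::data.table(chrom = character(), pos = integer(),
                                              strand = character(), count = numeric())
  occupancy_track(ct, library_size = library_size, normalized = normalized)
}
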