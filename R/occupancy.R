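#' Record nascent-RNA 3' ends from aligned reads
#'
#' In NET-seq the 5' end of the sequencing read corresponds to the 3' end of
#' the nascent RNA fragment; one count is placed at the genomic coordinate of
#' each read's 5'-most aligned base. Under the default fr-firststrand library
#' convention the read aligns antisense to the nascent RNA, so the transcript
#' strand is the opposite of the alignment strand.
#'
#' @param reads A `read_records` data frame (see [simulate_misprimed_reads()]):
#'   `chrom`, `start`, `end` (0-based half-open), `alignment_strand`,
#'   `barcode`.
#' @param chrom_names optional character vector of known chromosomes; reads on
#'   other chromosomes are skipped with a warning and tallied.
#' @param orientation `"fr-firststrand"` (default; transcript strand opposite
#'   the alignment strand) or `"fr-secondstrand"`.
#' @return A raw [occupancy_track()] with `library_size` equal to the number
#'   of recorded reads. The number of skipped reads is attached as attribute
#'   `"skipped"`.
#' @export
record_three_prime_ends <- function(reads, chrom_names = NULL,
                                    orientation = c("fr-firststrand",
                                                    "fr-secondstrand")) {
  orientation <- match.arg(orientation)
  reads <- as.data.frame(reads)
  skipped <- 0L
  if (!is.null(chrom_names)) {
    bad <- !(reads$chrom %in% chrom_names)
    skipped <- sum(bad)
    if (skipped)
      warning(sprintf("skipping %d read(s) on unknown chromosome(s): %s",
                      skipped, paste(unique(reads$chrom[bad]), collapse = ", ")))
    reads <- reads[!bad, , drop = FALSE]
  }
  if (!nrow(reads)) {
    tr <- occupancy_track(data.frame(chrom = character(), pos = integer(),
                                     strand = character(), count = numeric()),
                          library_size = 0)
    attr(tr, "skipped") <- skipped
    return(tr)
  }
  if (any(reads$end <= reads$start)) stop("read records with end <= start")
  pos <- ifelse(reads$alignment_strand == "+", reads$start, reads$end - 1L)
  tstrand <- if (orientation == "fr-firststrand") {
    ifelse(reads$alignment_strand == "+", "-", "+")
  } else {
    reads$alignment_strand
  }
  dt <- data.table::data.table(chrom = reads$chrom, pos = pos, strand = tstrand)
  dt <- dt[, list(count = .N), by = c("chrom", "pos", "strand")]
  tr <- occupancy_track(dt, library_size = nrow(reads))
  attr(tr, "skipped") <- skipped
  tr
}

#' Remove reverse-transcription mispriming artifacts
#'
#' Removes every read whose hexamer molecular barcode equals the 6 genomic
#' bases immediately downstream (in transcript orientation) of the recorded
#' 3'-end position — the signature of internal RT priming, where the barcode
#' is templated by genomic sequence rather than the random linker. Reads whose
#' 3' end lies within 6 bp of a chromosome end cannot be checked and are
#' retained with a flag.
#'
#' @param reads A `read_records` data frame.
#' @param genome A [Biostrings::DNAStringSet] covering all read chromosomes.
#' @param orientation library orientation, as in [record_three_prime_ends()].
#' @return List with `reads` (retained records, with a logical `edge_flagged`
#'   column) and `removed` (count of misprimed reads removed).
#' @export
filter_mispriming <- function(reads, genome,
                              orientation = c("fr-firststrand",
                                              "fr-secondstrand")) {
  orientation <- match.arg(orientation)
  reads <- as.data.frame(reads)
  if (!all(reads$chrom %in% names(genome)))
    stop("genome does not cover all read chromosomes")
  pos <- ifelse(reads$alignment_strand == "+", reads$start, reads$end - 1L)
  tstrand <- if (orientation == "fr-firststrand") {
    ifelse(reads$alignment_strand == "+", "-", "+")
  } else {
    reads$alignment_strand
  }
  adj <- adjacent_hexamer(genome, reads$chrom, pos, tstrand)
  edge <- is.na(adj)
  misprimed <- !edge & reads$barcode == adj
  out <- reads[!misprimed, , drop = FALSE]
  out$edge_flagged <- edge[!misprimed]
  class(out) <- c("read_records", "data.frame")
  list(reads = out, removed = sum(misprimed))
}

#' Normalize a track to reads per million mapped reads
#'
#' @param track A raw [occupancy_track()].
#' @return The track with every count multiplied by `1e6 / library_size` and
#'   the `normalized` flag set. Normalizing an already-normalized track, or a
#'   track with zero library size, is an error.
#' @export
normalize_per_million <- function(track) {
  if (track$normalized) stop("track is already normalized")
  if (track$library_size == 0) stop("cannot normalize a track with library_size 0")
  ct <- data.table::copy(track$counts)
  ct[, count := count * 1e6 / track$library_size]
  occupancy_track(ct, library_size = track$library_size, normalized = TRUE)
}

#' Per-gene RPKM
#'
#' RPKM = reads in the gene (strand-matched) / (gene length in kb x library
#' size in millions), from a raw track.
#'
#' @param track A raw [occupancy_track()].
#' @param annotation A [tx_annotation()].
#' @return Data frame with `gene_id` and `rpkm`.
#' @export
gene_rpkm <- function(track, annotation) {
  if (track$normalized) stop("gene_rpkm expects a raw track")
  len <- tx_length(annotation)
  if (any(len == 0)) stop("zero-length gene in annotation")
  reads <- unit_sums(track, annotation)
  data.frame(gene_id = annotation$gene_id,
             rpkm = reads / (len / 1000) / (track$library_size / 1e6),
             stringsAsFactors = FALSE)
}

#' Squared Pearson correlation between replicate RPKM vectors
#'
#' Warns (does not abort) when R^2 falls below the configured threshold:
#' replicates of mutant strains are accepted at R^2 >= 0.75, wild-type at
#' 0.97.
#'
#' @param rpkm_a,rpkm_b data frames from [gene_rpkm()] over the same genes.
#' @param threshold warning threshold on R^2 (default 0.75, the mutant
#'   acceptance bar).
#' @return The squared Pearson correlation.
#' @export
replicate_correlation <- function(rpkm_a, rpkm_b, threshold = 0.75) {
  m <- merge(rpkm_a, rpkm_b, by = "gene_id", suffixes = c("_a", "_b"))
  if (nrow(m) < 2) stop("need at least 2 matched genes for correlation")
  r2 <- cor(m$rpkm_a, m$rpkm_b)^2
  if (is.na(r2)) stop("correlation undefined (zero variance)")
  if (r2 < threshold)
    warning(sprintf("replicate R^2 = %.3f below threshold %.2f", r2, threshold))
  r2
}

#' Merge raw replicate tracks
#'
#' Position-wise sum of raw tracks with summed library sizes, followed by
#' per-million renormalization.
#'
#' @param ... Two or more raw [occupancy_track()]s.
#' @param renormalize apply [normalize_per_million()] to the merge (default
#'   `TRUE`, the standard pipeline behavior).
#' @return The merged track.
#' @export
merge_replicates <- function(..., renormalize = TRUE) {
  tracks <- list(...)
  if (length(tracks) == 1 && is.list(tracks[[1]]) &&
      !inherits(tracks[[1]], "occupancy_track"))
    tracks <- tracks[[1]]
  if (length(tracks) < 2) stop("need at least two tracks to merge")
  if (any(vapply(tracks, function(t) t$normalized, logical(1))))
    stop("cannot merge normalized tracks; merge raw tracks and renormalize")
  ct <- data.table::rbindlist(lapply(tracks, function(t) t$counts))
  ct <- ct[, list(count = sum(count)), by = c("chrom", "pos", "strand")]
  merged <- occupancy_track(ct, library_size = sum(vapply(tracks, function(t)
    t$library_size, numeric(1))))
  if (renormalize) normalize_per_million(merged) else merged
}

#' Build a per-unit read count table
#'
#' Strand-matched read sums per transcription unit (sense and antisense) per
#' sample, in the form consumed by external differential-expression tools.
#'
#' @param tracks named list of raw [occupancy_track()]s, one per sample.
#' @param annotation A [tx_annotation()] that may include antisense units
#'   (rows with `type == "antisense"`, ids prefixed `"anti"`).
#' @return Data frame with `unit_id` and one integer column per sample.
#' @export
build_count_table <- function(tracks, annotation) {
  if (is.null(names(tracks)) || any(names(tracks) == ""))
    stop("tracks must be a named list (one name per sample)")
  if (anyDuplicated(annotation$gene_id)) stop("duplicate unit identifiers")
  if (any(vapply(tracks, function(t) t$normalized, logical(1))))
    stop("build_count_table expects raw tracks")
  out <- data.frame(unit_id = annotation$gene_id, stringsAsFactors = FALSE)
  for (s in names(tracks)) out[[s]] <- as.integer(unit_sums(tracks[[s]], annotation))
  out
}
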