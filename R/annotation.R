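#' Transcription-unit annotation tables
#'
#' Annotations are plain data frames of class `tx_annotation` with one row per
#' transcription unit and columns:
#' \describe{
#'   \item{gene_id}{unique identifier; antisense units are prefixed `"anti"`}
#'   \item{chrom, start, end}{0-based half-open genomic span}
#'   \item{strand}{`"+"` or `"-"`}
#'   \item{tss, polya}{0-based positions of the transcription start site and
#'     the poly(A) site (`tss == start` on `+`, `end - 1` on `-`)}
#'   \item{intron_start, intron_end}{0-based half-open intron span, `NA` for
#'     intronless units; the 5' splice site is the intron boundary nearer the
#'     TSS, the 3' splice site the boundary nearer the poly(A) site}
#'   \item{type}{`"gene"` or `"antisense"`}
#' }
#'
#' @param df data frame with the columns above.
#' @return A `tx_annotation` data frame.
#' @export
tx_annotation <- function(df) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "tss", "polya",
            "intron_start", "intron_end", "type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(df$end <= df$start)) stop("empty transcription unit span")
  df <- as.data.frame(df)[, need]
  class(df) <- c("tx_annotation", "data.frame")
  df
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat(sprintf("<tx_annotation> %d units (%d sense, %d antisense), %d with introns\n",
              nrow(x), sum(x$type == "gene"), sum(x$type == "antisense"),
              sum(!is.na(x$intron_start))))
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

# gene length in bp
tx_length <- function(ann) ann$end - ann$start

# 5'/3' splice-site genomic positions (0-based, position of the first intronic
# base at the 5'SS and the last intronic base at the 3'SS, in transcript
# orientation)
splice_sites <- function(ann) {
  plus <- ann$strand == "+"
  data.frame(
    gene_id = ann$gene_id,
    ss5 = ifelse(plus, ann$intron_start, ann$intron_end - 1L),
    ss3 = ifelse(plus, ann$intron_end - 1L, ann$intron_start)
  )
}

#' Write an annotation to GFF3
#'
#' Units are written as `gene` features (1-based inclusive coordinates, per
#' the GFF3 convention) and introns as child `intron` features.
#'
#' @param ann A [tx_annotation()] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand,
    type = "gene",
    ID = ann$gene_id
  )
  has_intron <- !is.na(ann$intron_start)
  if (any(has_intron)) {
    gi <- GenomicRanges::GRanges(
      seqnames = ann$chrom[has_intron],
      ranges = IRanges::IRanges(start = ann$intron_start[has_intron] + 1L,
                                end = ann$intron_end[has_intron]),
      strand = ann$strand[has_intron],
      type = "intron",
      ID = paste0(ann$gene_id[has_intron], "_intron"),
      Parent = ann$gene_id[has_intron]
    )
    S4Vectors::mcols(gr)$Parent <- NA_character_
    gr <- c(gr, gi)
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an annotation written by [write_annotation_gff3()]
#'
#' @param path GFF3 file path.
#' @return A [tx_annotation()] table (coordinates converted back to 0-based
#'   half-open).
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  introns <- gr[gr$type == "intron"]
  df <- data.frame(
    gene_id = as.character(genes$ID),
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes) - 1L,
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    stringsAsFactors = FALSE
  )
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$polya <- ifelse(df$strand == "+", df$end - 1L, df$start)
  df$intron_start <- NA_integer_
  df$intron_end <- NA_integer_
  if (length(introns)) {
    parent <- vapply(introns$Parent, function(p) as.character(p)[1], character(1))
    idx <- match(parent, df$gene_id)
    df$intron_start[idx] <- GenomicRanges::start(introns) - 1L
    df$intron_end[idx] <- GenomicRanges::end(introns)
  }
  df$type <- ifelse(startsWith(df$gene_id, "anti"), "antisense", "gene")
  tx_annotation(df)
}
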