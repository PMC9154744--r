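# Small deterministic fixtures built in code.

# annotation of intronless genes laid head-to-tail on one chromosome
toy_ann <- function(lens, strands = rep("+", length(lens)), chrom = "chrT",
                    gap = 200L, offset = 300L) {
  starts <- offset + c(0L, cumsum(head(lens + gap, -1)))
  ends <- starts + lens
  tx_annotation(data.frame(
    gene_id = sprintf("g%02d", seq_along(lens)), chrom = chrom,
    start = starts, end = ends, strand = strands,
    tss = ifelse(strands == "+", starts, ends - 1L),
    polya = ifelse(strands == "+", ends - 1L, starts),
    intron_start = NA_integer_, intron_end = NA_integer_,
    type = "gene", stringsAsFactors = FALSE))
}

# occupancy track from per-gene count vectors given in transcript orientation
# (element 1 = TSS); extra is a data.frame of additional (chrom,pos,strand,count)
track_from_counts <- function(ann, counts_list, extra = NULL,
                              library_size = NULL) {
  parts <- lapply(seq_len(nrow(ann)), function(i) {
    v <- counts_list[[i]]
    stopifnot(length(v) == ann$end[i] - ann$start[i])
    if (ann$strand[i] == "-") v <- rev(v)
    data.frame(chrom = ann$chrom[i],
               pos = seq.int(ann$start[i], ann$end[i] - 1L),
               strand = ann$strand[i], count = v)
  })
  if (!is.null(extra)) parts <- c(parts, list(extra))
  occupancy_track(do.call(rbind, parts), library_size = library_size)
}

# uniform-coverage track over gene bodies plus flanks, both strands
uniform_track <- function(ann, value = 1, flank = 300L) {
  parts <- lapply(seq_len(nrow(ann)), function(i) {
    pos <- seq.int(max(0L, ann$start[i] - flank), ann$end[i] + flank - 1L)
    rbind(data.frame(chrom = ann$chrom[i], pos = pos, strand = "+", count = value),
          data.frame(chrom = ann$chrom[i], pos = pos, strand = "-", count = value))
  })
  dt <- data.table::rbindlist(parts)
  dt <- dt[, list(count = max(count)), by = c("chrom", "pos", "strand")]
  occupancy_track(dt)
}

pause_key <- function(d) paste(d$chrom, d$pos, d$strand)

# a small simulated dataset shared across tests (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_genes = 40, n_chrom = 1, chrom_length = 50000,
                               seed = 11)
      toy <- generate_toy_genome(cfg)
      sim <- simulate_occupancy(toy$annotation, cfg)
      cache <<- list(cfg = cfg, genome = toy$genome, ann = toy$annotation,
                     sim = sim)
    }
    cache
  }
})
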