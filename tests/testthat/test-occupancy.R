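test_that("3'-end recording follows the fr-firststrand convention", {
  reads <- data.frame(chrom = "chrT", start = 100L, end = 175L,
                      alignment_strand = "-", barcode = "ACGTAC")
  tr <- record_three_prime_ends(reads)
  expect_equal(tr$counts$pos, 174L)
  expect_equal(tr$counts$strand, "+")
  expect_equal(tr$counts$count, 1L)
  # plus-strand alignment: 5'-most base is the start; transcript strand "-"
  reads2 <- data.frame(chrom = "chrT", start = 100L, end = 175L,
                       alignment_strand = "+", barcode = "ACGTAC")
  tr2 <- record_three_prime_ends(reads2)
  expect_equal(tr2$counts$pos, 100L)
  expect_equal(tr2$counts$strand, "-")
})

test_that("empty input, conservation and unknown-chromosome handling", {
  empty <- record_three_prime_ends(
    data.frame(chrom = character(), start = integer(), end = integer(),
               alignment_strand = character(), barcode = character()))
  expect_equal(track_total(empty), 0)
  expect_equal(empty$library_size, 0)

  sm <- small_sim()
  reads <- simulate_misprimed_reads(sm$genome, sm$ann, n_reads = 1000, seed = 9)
  tr <- record_three_prime_ends(reads)
  expect_equal(track_total(tr), 1000)
  expect_equal(tr$library_size, 1000)

  reads$chrom[1:7] <- "chrUnknown"
  expect_warning(tr2 <- record_three_prime_ends(reads, chrom_names = names(sm$genome)),
                 "chrUnknown")
  expect_equal(attr(tr2, "skipped"), 7L)
  expect_equal(track_total(tr2), 993)
})

test_that("reversing every alignment strand swaps the strand tracks exactly", {
  sm <- small_sim()
  reads <- simulate_misprimed_reads(sm$genome, sm$ann, n_reads = 2000, seed = 10)
  fwd <- record_three_prime_ends(reads)
  flipped <- reads
  flipped$alignment_strand <- ifelse(reads$alignment_strand == "+", "-", "+")
  # flipping the alignment strand moves the recorded 5' end to the other read
  # extremity, so compare per-strand totals, which must swap exactly
  rev <- record_three_prime_ends(flipped)
  tot <- function(t, s) sum(t$counts$count[t$counts$strand == s])
  expect_equal(tot(fwd, "+"), tot(rev, "-"))
  expect_equal(tot(fwd, "-"), tot(rev, "+"))
})

test_that("mispriming filter applies the exact-match rule on both strands", {
  genome <- Biostrings::DNAStringSet(c(chrF = paste(rep("ACGTAC", 40), collapse = "")))
  # plus-strand transcript: 3' end at pos, adjacent 6-mer = genome[pos+2..pos+7]
  pos <- 11L  # 0-based; adjacent bases 12..17 (0-based) = "ACGTAC"
  expect_equal(netseqr:::adjacent_hexamer(genome, "chrF", pos, "+"), "ACGTAC")
  read_minus <- data.frame(chrom = "chrF", start = pos + 1L - 20L, end = pos + 1L,
                           alignment_strand = "-", barcode = "ACGTAC")
  res <- filter_mispriming(read_minus, genome)
  expect_equal(res$removed, 1L)
  read_keep <- transform(read_minus, barcode = "ACGTAA")
  expect_equal(filter_mispriming(read_keep, genome)$removed, 0L)

  # minus-strand transcript: adjacent bases upstream, reverse-complemented
  hx <- netseqr:::adjacent_hexamer(genome, "chrF", 20L, "-")
  expect_equal(hx, as.character(Biostrings::reverseComplement(
    Biostrings::subseq(genome[["chrF"]], 15, 20))))
  read_plus <- data.frame(chrom = "chrF", start = 20L, end = 60L,
                          alignment_strand = "+", barcode = hx)
  expect_equal(filter_mispriming(read_plus, genome)$removed, 1L)

  # 3' end within 6 bp of the chromosome end: retained and flagged
  edge <- data.frame(chrom = "chrF", start = 236L, end = 240L,
                     alignment_strand = "-", barcode = "AAAAAA")
  res_edge <- filter_mispriming(edge, genome)
  expect_equal(res_edge$removed, 0L)
  expect_true(all(res_edge$reads$edge_flagged))
})

test_that("per-million normalization follows its formula and contract", {
  tr <- occupancy_track(data.frame(chrom = "c", pos = c(5L, 9L), strand = "+",
                                   count = c(4, 6)), library_size = 2e6)
  nm <- normalize_per_million(tr)
  expect_equal(nm$counts$count, c(2, 3))
  expect_true(nm$normalized)
  expect_error(normalize_per_million(nm), "already normalized")
  tr2 <- occupancy_track(data.frame(chrom = "c", pos = 1L, strand = "+", count = 5))
  expect_equal(track_total(normalize_per_million(tr2)), 1e6)
  tr0 <- occupancy_track(data.frame(chrom = character(), pos = integer(),
                                    strand = character(), count = numeric()),
                         library_size = 0)
  expect_error(normalize_per_million(tr0), "library_size 0")
})

test_that("gene RPKM matches its formula and a brute-force interval oracle", {
  ann <- toy_ann(1000L)
  tr <- track_from_counts(ann, list(rep(0L, 1000L)),
                          extra = data.frame(chrom = "chrT",
                                             pos = ann$start + 0:99,
                                             strand = "+", count = 1L),
                          library_size = 1e6)
  expect_equal(gene_rpkm(tr, ann)$rpkm, 100)
  tr0 <- track_from_counts(ann, list(rep(0L, 1000L)), library_size = 1e6)
  expect_equal(gene_rpkm(tr0, ann)$rpkm, 0)

  sm <- small_sim()
  rp <- gene_rpkm(sm$sim$rep1, sm$ann)
  set.seed(42)
  for (i in sample(nrow(sm$ann), 20)) {
    a <- sm$ann[i, ]
    ct <- as.data.frame(sm$sim$rep1$counts)
    manual <- sum(ct$count[ct$chrom == a$chrom & ct$strand == a$strand &
                             ct$pos >= a$start & ct$pos < a$end])
    expect_equal(rp$rpkm[i],
                 manual / ((a$end - a$start) / 1000) /
                   (sm$sim$rep1$library_size / 1e6))
  }
})

test_that("replicate correlation is squared Pearson with a warning threshold", {
  ra <- data.frame(gene_id = c("a", "b", "c"), rpkm = c(1, 2, 3))
  expect_equal(replicate_correlation(ra, ra), 1.0)
  rb <- data.frame(gene_id = c("a", "b", "c"), rpkm = c(3, 1, 2))
  # hand-check: cor((1,2,3),(3,1,2)) = -1/2, squared = 1/4
  expect_warning(r2 <- replicate_correlation(ra, rb), "below threshold")
  expect_equal(r2, 0.25)
  expect_silent(replicate_correlation(ra, rb, threshold = 0.2))
  expect_error(replicate_correlation(ra[1, ], ra[1, ]), "2 matched genes")
})

test_that("replicate merge sums, renormalizes, and is associative", {
  sm <- small_sim()
  a <- sm$sim$rep1; b <- sm$sim$rep2
  m_ab <- merge_replicates(a, b)
  expect_true(m_ab$normalized)
  expect_equal(m_ab$library_size, a$library_size + b$library_size)
  # identical tracks: merged normalized values equal each input's normalized values
  m_aa <- merge_replicates(a, a)
  na <- normalize_per_million(a)
  expect_equal(m_aa$counts, na$counts)
  # associativity on raw merges
  ab <- merge_replicates(a, b, renormalize = FALSE)
  ab_b <- merge_replicates(ab, b, renormalize = FALSE)
  abb <- merge_replicates(list(a, b, b), renormalize = FALSE)
  expect_equal(ab_b$counts, abb$counts)
  expect_equal(ab_b$library_size, abb$library_size)
  expect_error(merge_replicates(m_ab, a), "normalized")
})

test_that("count tables partition reads by strand over sense and antisense units", {
  ann <- toy_ann(c(800L, 800L), strands = c("+", "-"))
  anti <- build_antisense_annotation(ann)
  full <- tx_annotation(rbind(as.data.frame(ann), as.data.frame(anti)))
  counts <- data.frame(chrom = "chrT",
                       pos = c(ann$start[1] + c(10L, 20L, 30L),
                               ann$start[1] + c(40L, 50L)),
                       strand = c("+", "+", "+", "-", "-"),
                       count = c(2, 1, 1, 3, 2))
  tr <- occupancy_track(counts)
  tab <- build_count_table(list(s1 = tr), full)
  expect_equal(tab[tab$unit_id == "g01", "s1"], 4L)
  expect_equal(tab[tab$unit_id == "antig01", "s1"], 5L)
  # all reads fall inside units, so the table total equals the library size
  expect_equal(sum(tab$s1), track_total(tr))
  empty <- occupancy_track(data.frame(chrom = character(), pos = integer(),
                                      strand = character(), count = numeric()),
                           library_size = 1)
  tab2 <- build_count_table(list(s1 = tr, s0 = empty), full)
  expect_true(all(tab2$s0 == 0L))
  dup <- rbind(as.data.frame(ann), as.data.frame(ann))
  expect_error(build_count_table(list(s1 = tr), dup), "duplicate")
})
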