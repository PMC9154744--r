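test_that("control loci are count-matched per gene and disjoint from real ones", {
  sm <- small_sim()
  tr <- sm$sim$truth
  p <- data.frame(chrom = tr$chrom, pos = tr$pos, strand = tr$strand,
                  gene_id = tr$gene_id)
  for (seed in 1:3) {
    ctrl <- shuffled_control_loci(p, sm$ann, seed = seed)
    expect_equal(table(ctrl$gene_id), table(p$gene_id))
    expect_length(intersect(pause_key(ctrl), pause_key(p)), 0)
  }
  # saturation: a gene with every position paused leaves no controls
  ann1 <- toy_ann(600L)
  sat <- data.frame(chrom = "chrT", pos = ann1$start + 0:599, strand = "+",
                    gene_id = "g01")
  expect_error(shuffled_control_loci(sat, ann1), "saturated")
})

test_that("sequence features are extracted strand-aware around the locus", {
  seq <- paste0(strrep("C", 40), "GTATA", strrep("C", 40))
  genome <- Biostrings::DNAStringSet(c(chrQ = seq))
  ann <- tx_annotation(data.frame(
    gene_id = c("gp", "gm"), chrom = "chrQ", start = c(5L, 5L),
    end = c(80L, 80L), strand = c("+", "-"), tss = c(5L, 79L),
    polya = c(79L, 5L), intron_start = NA_integer_, intron_end = NA_integer_,
    type = "gene", stringsAsFactors = FALSE))
  # center base 0-based 42 is the middle "A" of "GTATA" (bases 40..44)
  real <- data.frame(chrom = "chrQ", pos = 42L, strand = "+", gene_id = "gp")
  ctrl <- data.frame(chrom = "chrQ", pos = 20L, strand = "+", gene_id = "gp")
  ft <- assemble_features(real, ctrl, genome, ann,
                          shape_table = synthetic_shape_table(constant = 32.1))
  row <- ft[ft$label == "real", ]
  expect_equal(as.character(row$trinuc), "TAT")
  expect_equal(as.character(row$base_p0), "A")
  expect_equal(as.character(row$base_m1), "T")
  expect_equal(row$twist, 32.1)
  expect_equal(ft$twist, rep(32.1, 2))

  # minus-strand locus at the same base reads the reverse complement
  realm <- data.frame(chrom = "chrQ", pos = 42L, strand = "-", gene_id = "gm")
  ftm <- assemble_features(realm, transform(ctrl, strand = "-", gene_id = "gm"),
                           genome, ann)
  expect_equal(as.character(ftm[ftm$label == "real", "trinuc"]), "ATA")

  # mirror invariance: reverse-complement the genome, flip strand and
  # coordinates -> identical sequence features
  L <- nchar(seq)
  genome_rc <- Biostrings::DNAStringSet(c(chrQ = as.character(
    Biostrings::reverseComplement(genome[[1]]))))
  ann_rc <- transform(ann, strand = c("-", "+"))
  real_rc <- transform(real, pos = L - 1L - 42L, strand = "-")
  ctrl_rc <- transform(ctrl, pos = L - 1L - 20L, strand = "-")
  ft_rc <- assemble_features(real_rc, ctrl_rc, genome_rc, tx_annotation(ann_rc),
                             shape_table = synthetic_shape_table(constant = 32.1))
  seq_cols <- c("trinuc", grep("^base_", names(ft), value = TRUE), "tm",
                "gc_window", "twist")
  for (col in seq_cols)
    expect_equal(as.character(ft_rc[[col]]), as.character(ft[[col]]),
                 label = col)
})

test_that("track-window features average the signal and edges are flagged", {
  genome <- Biostrings::DNAStringSet(c(chrQ = strrep("ACGT", 30)))
  ann <- toy_ann(100L, chrom = "chrQ", offset = 10L)
  const <- occupancy_track(data.frame(chrom = "chrQ", pos = 0:119,
                                      strand = "+", count = 5))
  real <- data.frame(chrom = "chrQ", pos = 60L, strand = "+", gene_id = "g01")
  ctrl <- data.frame(chrom = "chrQ", pos = 80L, strand = "+", gene_id = "g01")
  ft <- assemble_features(real, ctrl, genome, ann, tracks = list(mnase = const),
                          track_window = 10)
  expect_equal(ft$track_mnase, c(5, 5))
  expect_false(any(ft$edge_flag))
  # a locus too close to the chromosome end keeps its row, flagged, with
  # missing sequence features
  edge <- data.frame(chrom = "chrQ", pos = 115L, strand = "+", gene_id = "g01")
  fte <- assemble_features(edge, ctrl, genome, ann)
  erow <- fte[fte$pos == 115L, ]
  expect_true(erow$edge_flag)
  expect_true(is.na(erow$tm))
})

test_that("melting temperature responds to GC content and window length", {
  tm <- melting_temperature(c(strrep("AT", 10), strrep("GC", 10)))
  expect_gt(tm[2], tm[1])
  expect_gt(melting_temperature(strrep("GC", 15)), tm[2])
  expect_true(is.na(melting_temperature("ACGTN")))
})

test_that("feature tests use Student's t with Bonferroni over tested features", {
  set.seed(5)
  n <- 500
  tab <- data.frame(label = rep(c("real", "control"), each = n),
                    gene_id = "g", chrom = "c", pos = 1, strand = "+",
                    edge_flag = FALSE)
  tab$shifted <- rnorm(2 * n) + ifelse(tab$label == "real", 2, 0)  # 2 sigma
  tab$noise1 <- rnorm(2 * n)
  tab$noise2 <- rnorm(2 * n)
  tab$flat <- 1
  tab$trinuc <- factor(sample(c("AAA", "TTT"), 2 * n, replace = TRUE))
  res <- feature_distribution_tests(tab)
  expect_true(res$skipped[res$feature == "trinuc"])
  expect_equal(res$note[res$feature == "flat"], "zero variance")
  m <- sum(!res$skipped)
  expect_equal(res$p_adjusted[!res$skipped],
               pmin(res$p[!res$skipped] * m, 1))
  expect_lt(res$p_adjusted[res$feature == "shifted"], 0.001)
  expect_gt(min(res$p_adjusted[res$feature %in% c("noise1", "noise2")]), 0.0)

  # null features stay non-significant in most seeds
  ok <- 0
  for (seed in 1:20) {
    set.seed(seed)
    tab$shifted <- rnorm(2 * n)
    r <- feature_distribution_tests(tab)
    if (all(r$p_adjusted[!r$skipped] >= 0.05)) ok <- ok + 1
  }
  expect_gte(ok, 17)
})

test_that("pause-flank FASTA export writes strand-aware sequences", {
  sm <- small_sim()
  tr <- head(sm$sim$truth, 20)
  loci <- data.frame(chrom = tr$chrom, pos = tr$pos, strand = tr$strand,
                     gene_id = tr$gene_id)
  path <- withr::local_tempfile(fileext = ".fa")
  export_pause_flank_fasta(loci, sm$genome, path, flank = 10)
  back <- Biostrings::readDNAStringSet(path)
  expect_equal(length(back), 20L)
  expect_true(all(Biostrings::width(back) == 21))
  i <- 1L
  fwd <- Biostrings::subseq(sm$genome[[loci$chrom[i]]],
                            loci$pos[i] - 9L, loci$pos[i] + 11L)
  if (loci$strand[i] == "-") fwd <- Biostrings::reverseComplement(fwd)
  expect_equal(as.character(back[[paste(loci$chrom[i], loci$pos[i],
                                        loci$strand[i], sep = ":")]]),
               as.character(fwd))
})
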