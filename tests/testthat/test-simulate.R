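test_that("generators are byte-identical under a fixed seed", {
  cfg <- simulation_config(n_genes = 50, n_chrom = 1, chrom_length = 60000,
                           seed = 7)
  a <- generate_toy_genome(cfg)
  b <- generate_toy_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$annotation, b$annotation)
  sa <- simulate_occupancy(a$annotation, cfg)
  sb <- simulate_occupancy(b$annotation, cfg)
  expect_identical(sa$rep1$counts, sb$rep1$counts)
  expect_identical(sa$truth, sb$truth)
  tdir <- withr::local_tempdir()
  write_simulation(sa, a$genome, a$annotation, cfg, file.path(tdir, "x"))
  write_simulation(sb, b$genome, b$annotation, cfg, file.path(tdir, "y"))
  expect_identical(readLines(file.path(tdir, "x", "genome.fa")),
                   readLines(file.path(tdir, "y", "genome.fa")))
  expect_identical(readLines(file.path(tdir, "x", "annotation.gff3")),
                   readLines(file.path(tdir, "y", "annotation.gff3")))
})

test_that("intron fraction controls splice-site records", {
  cfg0 <- simulation_config(n_genes = 30, n_chrom = 1, chrom_length = 60000,
                            intron_fraction = 0, seed = 2)
  expect_true(all(is.na(generate_toy_genome(cfg0)$annotation$intron_start)))
  cfg1 <- simulation_config(n_genes = 30, n_chrom = 1, chrom_length = 60000,
                            intron_fraction = 1, seed = 2)
  ann <- generate_toy_genome(cfg1)$annotation
  expect_true(all(!is.na(ann$intron_start)))
  expect_true(all(ann$intron_start > ann$start & ann$intron_end < ann$end))
})

test_that("an over-budget gene set raises an explicit sizing error", {
  cfg <- simulation_config(n_genes = 100, n_chrom = 1, chrom_length = 20000,
                           seed = 1)
  expect_error(generate_toy_genome(cfg), "budget")
})

test_that("written GFF3 re-parses to the same annotation and total length", {
  cfg <- simulation_config(n_genes = 200, gene_length_range = c(800, 3000),
                           n_chrom = 2, chrom_length = 300000, seed = 5)
  toy <- generate_toy_genome(cfg)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(toy$annotation, path)
  back <- read_annotation_gff3(path)
  back <- back[match(toy$annotation$gene_id, back$gene_id), ]
  rownames(back) <- NULL
  expect_equal(sum(back$end - back$start),
               sum(toy$annotation$end - toy$annotation$start))
  for (col in c("chrom", "start", "end", "strand", "tss", "polya",
                "intron_start", "intron_end"))
    expect_equal(back[[col]], toy$annotation[[col]], ignore_attr = TRUE)
})

test_that("background counts match the configured NB mean when no pauses are planted", {
  cfg <- simulation_config(n_genes = 20, n_chrom = 1, chrom_length = 40000,
                           pause_rate = 0, expression_mean_range = c(4, 4),
                           antisense_fraction = 0, seed = 3)
  toy <- generate_toy_genome(cfg)
  sim <- simulate_occupancy(toy$annotation, cfg)
  expect_identical(nrow(sim$truth), 0L)
  len <- toy$annotation$end - toy$annotation$start
  means <- netseqr:::unit_sums(sim$rep1, toy$annotation) / len
  se <- sqrt((4 + 16 / cfg$nb_dispersion) / len)
  expect_true(all(abs(means - 4) < 3 * se))
})

test_that("reproducibility flags and strong-pause detectability behave as configured", {
  cfg <- simulation_config(n_genes = 20, n_chrom = 1, chrom_length = 40000,
                           reproducible_fraction = 1, seed = 4)
  toy <- generate_toy_genome(cfg)
  expect_true(all(simulate_occupancy(toy$annotation, cfg)$truth$reproducible))

  # a 10x pause over a 5 reads/bp background exceeds the background's 99.9th
  # percentile in nearly every seed
  hits <- 0L; total <- 0L
  q999 <- qnbinom(0.999, mu = 5, size = 10)
  for (s in 1:30) {
    cfg <- simulation_config(n_genes = 4, n_chrom = 1, chrom_length = 8000,
                             expression_mean_range = c(5, 5),
                             pause_strength_range = c(10, 10),
                             pause_rate = 2, reproducible_fraction = 1,
                             antisense_fraction = 0, seed = s)
    toy <- generate_toy_genome(cfg)
    sim <- simulate_occupancy(toy$annotation, cfg)
    if (!nrow(sim$truth)) next
    v <- vapply(seq_len(nrow(sim$truth)), function(k)
      netseqr:::positions_signal(sim$rep1, sim$truth$chrom[k],
                                 sim$truth$pos[k], sim$truth$strand[k]),
      numeric(1))
    hits <- hits + sum(v > q999); total <- total + nrow(sim$truth)
  }
  expect_gt(hits / total, 0.95)
})

test_that("junction counts follow psi and the closed-form splicing index", {
  cfg <- simulation_config(n_genes = 30, n_chrom = 1, chrom_length = 60000,
                           intron_fraction = 1, seed = 6)
  ann <- generate_toy_genome(cfg)$annotation
  j1 <- simulate_junction_counts(ann, psi = 1, depth = 500, seed = 1)
  expect_true(all(j1$unspliced5 == 0 & j1$unspliced3 == 0))
  expect_identical(j1, simulate_junction_counts(ann, psi = 1, depth = 500, seed = 1))
  expect_error(simulate_junction_counts(ann, psi = 1.2, depth = 10), "psi")

  j <- splicing_index(simulate_junction_counts(ann, psi = 0.5, depth = 10000,
                                               seed = 2))
  # closed form on expected counts: 2 * psi * d / ((1 - psi) * d) = 2
  expect_lt(abs(mean(j$si) - 2), 0.1)
  expect_true(all(abs(j$si - 2) < 0.3))
})

test_that("mispriming simulation matches its analytic rates", {
  sm <- small_sim()
  r0 <- simulate_misprimed_reads(sm$genome, sm$ann, n_reads = 20000,
                                 misprime_fraction = 0, seed = 1)
  f0 <- filter_mispriming(r0, sm$genome)
  # chance collision rate 4^-6 per read
  expect_lt(f0$removed / 20000, 4^-6 * 10 + 1e-3)
  r1 <- simulate_misprimed_reads(sm$genome, sm$ann, n_reads = 500,
                                 misprime_fraction = 1, seed = 2)
  expect_identical(filter_mispriming(r1, sm$genome)$removed, 500L)

  r <- simulate_misprimed_reads(sm$genome, sm$ann, n_reads = 10000,
                                misprime_fraction = 0.2, seed = 3)
  removed <- filter_mispriming(r, sm$genome)$removed
  ci <- qbinom(c(0.005, 0.995), 10000, 0.2 + 0.8 * 4^-6)
  expect_gte(removed, ci[1]); expect_lte(removed, ci[2])
})
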