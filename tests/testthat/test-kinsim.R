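test_that("genome generation is seed-deterministic and respects composition", {
  g1 <- generate_genome(1000, 0.5, seed = 7)
  g2 <- generate_genome(1000, 0.5, seed = 7)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_equal(nrow(g1$planted), 0)

  gc <- generate_genome(50000, 0.36, seed = 3)
  comp <- table(strsplit(as.character(gc$genome[[1]]), "")[[1]])
  expect_equal(unname((comp[["G"]] + comp[["C"]]) / 50000), 0.36,
               tolerance = 0.02)

  multi <- generate_genome(c(chrA = 500, chrB = 300), 0.5, seed = 1)
  expect_identical(names(multi$genome), c("chrA", "chrB"))
})

test_that("planted motifs appear with resolved IUPAC and correct ground truth", {
  g <- generate_genome(4000, 0.5, list(plant_spec("GATC", 1, 5, 8.57)),
                       seed = 5)
  expect_equal(nrow(g$planted), 5)
  expect_true(all(g$planted$motif_id == "GATC"))
  seq <- as.character(g$genome[[1]])
  expect_gte(length(gregexpr("GATC", seq)[[1]]), 5)
  expect_true(all(substring(seq, g$planted$start + 1, g$planted$start + 4) ==
                    "GATC"))
  expect_identical(g$planted$focal_pos, g$planted$start + 1L)

  # degenerate positions resolved to concrete bases per occurrence
  ggn <- generate_genome(4000, 0.5, list(plant_spec("GGNGGNGGNGGN", 2, 3)),
                         seed = 9)
  seqs <- substring(as.character(ggn$genome[[1]]),
                    ggn$planted$start + 1, ggn$planted$start + 12)
  expect_true(all(grepl("^GG[ACGT]GG[ACGT]GG[ACGT]GG[ACGT]$", seqs)))

  # minus-strand plant inserts the reverse complement on the plus strand
  mins <- generate_genome(2000, 0.5,
                          list(plant_spec("GGATCA", 0, 3, strand = "-")),
                          seed = 2)
  ins <- substring(as.character(mins$genome[[1]]),
                   mins$planted$start + 1, mins$planted$start + 6)
  expect_true(all(ins == "TGATCC"))
  expect_identical(mins$planted$focal_pos, mins$planted$start + 5L)

  expect_error(generate_genome(20, 0.5, list(plant_spec("GATC", 0, 10)),
                               seed = 1),
               "footprint")
  expect_error(plant_spec("GAXC", 0, 1), "IUPAC")
})

test_that("degenerate dispersion collapses IPDs to configured mean products", {
  cfg0 <- kinetics_config(log_sigma = 0, outlier_prob = 0,
                          neighbor_mismatch_prob = 0)
  g <- generate_genome(500, 0.5, list(plant_spec("GATC", 1, 2, 8)), seed = 3)
  nat <- simulate_reads(g, g$planted, cfg0, "native", seed = 4)
  expect_true(all(nat$ipd > 0))
  base_vals <- c(A = 1.38, C = 0.95, G = 1.00, T = 0.65)
  focal_key <- paste(g$planted$contig, g$planted$focal_pos, g$planted$strand)
  at_focal <- paste(nat$contig, nat$pos, nat$strand) %in% focal_key
  expect_true(all(nat$ipd[at_focal] == 1.38 * 8))
  expect_true(all(nat$ipd[!at_focal] == base_vals[nat$ref_base[!at_focal]]))

  # wga mode: modification multiplier must NOT be applied
  wga <- simulate_reads(g, g$planted, cfg0, "wga", seed = 4)
  at_focal_w <- paste(wga$contig, wga$pos, wga$strand) %in% focal_key
  expect_true(all(wga$ipd[at_focal_w] == 1.38))
})

test_that("simulated IPD means are calibrated and coverage is Poisson", {
  cfg <- kinetics_config(outlier_prob = 0, neighbor_mismatch_prob = 0)
  g <- generate_genome(12000, 0.5, seed = 21)
  obs <- simulate_reads(g, NULL, cfg, "wga", seed = 22)
  means <- tapply(obs$ipd, obs$ref_base, mean)
  expect_equal(as.vector(means[c("A", "C", "G", "T")]),
               c(1.38, 0.95, 1.00, 0.65), tolerance = 0.02)

  # observation counts at 10,000+ site-strands fit Poisson(30)
  counts_obs <- table(paste(obs$pos, obs$strand))
  cnt <- c(as.integer(counts_obs), integer(2 * 12000 - length(counts_obs)))
  brk <- c(-Inf, 18:42, Inf)
  o <- table(cut(cnt, brk))
  p <- diff(ppois(c(-Inf, 18:42, Inf), 30))
  expect_gt(chisq.test(as.integer(o), p = p)$p.value, 0.01)
})

test_that("native/WGA contrast recovers the planted multiplier", {
  g <- generate_genome(30000, 0.5, list(plant_spec("GATC", 1, 120, 4)),
                       seed = 31)
  cfg <- kinetics_config()
  nat <- simulate_reads(g, g$planted, cfg, "native", seed = 32)
  wga <- simulate_reads(g, g$planted, cfg, "wga", seed = 33)
  key <- paste(g$planted$contig, g$planted$focal_pos, g$planted$strand)
  fn <- mean(nat$ipd[paste(nat$contig, nat$pos, nat$strand) %in% key])
  fw <- mean(wga$ipd[paste(wga$contig, wga$pos, wga$strand) %in% key])
  expect_equal(fn / fw, 4, tolerance = 0.1)
})

test_that("dataset writing round-trips and uses the stated conventions", {
  g <- generate_genome(800, 0.5, list(plant_spec("GATC", 1, 3, 2)), seed = 41)
  obs <- simulate_reads(g, g$planted, kinetics_config(coverage_per_strand = 3),
                        "native", seed = 42)
  dir <- withr::local_tempdir()
  write_dataset(obs, dir, planted = g$planted, genome = g$genome)
  back <- read_dataset(dir)
  expect_equal(as.data.frame(back), as.data.frame(obs))

  # TSV pos column is 1-based
  first <- readr::read_tsv(file.path(dir, "reads.tsv"), n_max = 1,
                           show_col_types = FALSE)
  expect_equal(first$pos, obs$pos[1] + 1)

  # BED is 0-based half-open: focal offset p appears as (p, p+1)
  bed <- read.table(file.path(dir, "planted.bed"), sep = "\t")
  expect_identical(bed$V2, g$planted$focal_pos)
  expect_identical(bed$V3, g$planted$focal_pos + 1L)
  expect_true(all(bed$V4 == "GATC:1"))
  expect_true(all(bed$V5 == 200))

  # genome FASTA round trip
  expect_identical(as.character(read_genome_fasta(file.path(dir, "genome.fa"))),
                   as.character(g$genome))

  # degenerate input: header-only file
  empty <- obs[0, ]
  write_dataset(empty, dir)
  expect_identical(nrow(read_dataset(dir)), 0L)
})
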