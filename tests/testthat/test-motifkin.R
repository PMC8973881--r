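test_that("IUPAC scanning reports both strands, degeneracy and overlaps", {
  # palindrome: both strands at the same start
  occ <- scan_motif(c(chr = "GGATCC"), "GATC")
  expect_equal(occ$start, c(1L, 1L))
  expect_setequal(occ$strand, c("+", "-"))

  # R = A/G
  expect_equal(nrow(scan_motif(c(a = "ACGCATG"), "ACGCRTG")), 1)
  expect_equal(nrow(scan_motif(c(a = "ACGCGTG"), "ACGCRTG")), 1)
  expect_equal(nrow(scan_motif(c(a = "ACGCTTG"), "ACGCRTG")), 0)

  # gapped motif: TGA at 0-2, TGCA at 11-14
  hit <- scan_motif(c(a = "TTGACCCCGGGGTGCAT"), "TGANNNNNNNNTGCA")
  expect_equal(hit$start[hit$strand == "+"], 1L)

  # overlapping matches all reported
  expect_equal(sum(scan_motif(c(a = "AAAA"), "AA")$strand == "+"), 3)

  expect_error(scan_motif(c(a = "ACGT"), "GAXC"), "X")
})

test_that("minus-strand scanning equals plus-strand scanning of the revcomp", {
  withr::with_seed(13, {
    g <- generate_genome(5000, 0.45, seed = 13)$genome
  })
  for (m in c("GAWTC", "ACGCRTG", "GGNGG")) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
    minus <- scan_motif(g, m)
    minus <- minus[minus$strand == "-", ]
    plus_rc <- scan_motif(g, rc)
    plus_rc <- plus_rc[plus_rc$strand == "+", ]
    expect_identical(minus$start, plus_rc$start)
  }
})

test_that("motif profiles read positions 5'-to-3' on the motif strand", {
  occ <- tibble::tibble(contig = "c1", start = 10L, strand = "+")
  sites <- make_sites(0:30, rep(2, 31))
  prof <- motif_profile(sites, occ, "ACGT", flank = 2)
  expect_equal(prof$mean_ipd, rep(2, 8))
  expect_equal(prof$se, rep(0, 8))
  expect_equal(prof$n_sites, rep(1L, 8))

  # mirrored-coordinate contract for minus-strand occurrences, on
  # strand-symmetric position-coded site values
  vals <- seq(1, 4, length.out = 31)
  sym <- dplyr::bind_rows(make_sites(0:30, vals, strand = "+"),
                          make_sites(0:30, vals, strand = "-"))
  m <- "ACGGT"
  occ_minus <- tibble::tibble(contig = "c1", start = 10L, strand = "-")
  occ_plus <- tibble::tibble(contig = "c1", start = 10L, strand = "+")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
  pm <- motif_profile(sym, occ_minus, m, flank = 3)
  pp <- motif_profile(sym, occ_plus, rc, flank = 3)
  mirrored <- pp$mean_ipd[match(nchar(m) - 1 - pm$rel_pos, pp$rel_pos)]
  expect_equal(pm$mean_ipd, mirrored)

  # missing sites are skipped, not imputed
  gap <- make_sites(c(8:12, 14), c(rep(2, 5), 9))
  pg <- motif_profile(gap, occ, "ACGT", flank = 1)
  expect_equal(pg$n_sites[pg$rel_pos == 3], 0L)
  expect_error(motif_profile(make_sites(100, 2), occ, "ACGT"), "usable")
})

test_that("rank-sum test matches enumeration and separates shifts", {
  out <- wilcoxon_ranksum(c(1, 2), c(3, 4))
  expect_equal(out$p_value, 1 / 3)
  expect_true(out$exact)
  expect_equal(out$statistic, 3)

  # identical multisets: p = 1 (tied, normal path)
  expect_equal(wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # exact path equals the enumeration oracle over a tie-free grid
  withr::with_seed(17, {
    for (sizes in list(c(2, 2), c(2, 5), c(3, 4), c(4, 4), c(5, 8), c(8, 20))) {
      for (rep in 1:5) {
        x <- sample(10000, sizes[1])
        y <- sample(10000, sizes[2]) + 0.5
        expect_equal(wilcoxon_ranksum(x, y)$p_value,
                     ranksum_exact_oracle(x, y), tolerance = 1e-12)
      }
    }
  })

  # clear separation
  withr::with_seed(18, {
    x <- rnorm(50)
  })
  expect_lt(wilcoxon_ranksum(x, x + 10)$p_value, 1e-6)
  expect_error(wilcoxon_ranksum(numeric(0), 1), "nonempty")
})

test_that("ratio of increase uses the same-base genome baseline", {
  sites <- dplyr::bind_rows(
    make_sites(0:99, rep(1, 100), ref_base = "A"),
    make_sites(100:199, rep(3, 100), ref_base = "G")
  )
  # occurrence whose focal position carries mean 2.0
  sites$mean_ipd[sites$pos == 50] <- 2.0
  occ <- tibble::tibble(contig = "c1", start = 49L, strand = "+")
  prof <- motif_profile(sites, occ, "NAN", flank = 0)
  roi <- ratio_of_increase(prof, sites, 1)
  expect_equal(roi$focal_base, "A")
  # genome A mean = (99 * 1 + 2) / 100; ratio against it, not against G sites
  expect_equal(roi$ratio_of_increase, 2 / mean(sites$mean_ipd[1:100]))
})

test_that("planted context multiplier is recovered by the ratio of increase", {
  g <- generate_genome(40000, 0.5,
                       list(plant_spec("GATC", 1, 200, 1,
                                       context = c("1" = 1.5))),
                       seed = 51)
  wga <- aggregate_sites(simulate_reads(g, g$planted, kinetics_config(),
                                        "wga", seed = 52))
  prof <- motif_profile(wga, planted_occurrences(g), "GATC")
  roi <- ratio_of_increase(prof, wga, 1)
  expect_equal(roi$ratio_of_increase[roi$focal_base == "A"], 1.5,
               tolerance = 0.05)
  expect_lt(roi$ranksum_p[roi$focal_base == "A"], 1e-6)

  # null motif: ratio ~ 1
  null_occ <- scan_motif(g$genome, "ATGCAT")
  null_prof <- motif_profile(wga, null_occ, "ATGCAT")
  null_roi <- ratio_of_increase(null_prof, wga, 4)
  expect_equal(null_roi$ratio_of_increase[1], 1, tolerance = 0.05)
})

test_that("native/WGA comparison is neutral on identical and null data", {
  sites <- make_sites(0:49, seq(0.5, 3, length.out = 50))
  loci <- tibble::tibble(contig = "c1", pos = 0:49, strand = "+")
  cmp <- compare_native_wga(sites, sites, loci)
  expect_equal(cmp$native_wga_fold, 1)
  expect_gt(cmp$native_wga_p, 0.9)
  expect_equal(cmp$n_skipped, 0L)
  expect_error(compare_native_wga(sites, make_sites(100, 1), loci), "shared")
})

test_that("null fold is calibrated across replicate locus subsets", {
  g <- generate_genome(20000, 0.5, seed = 61)
  cfg <- kinetics_config()
  a <- aggregate_sites(simulate_reads(g, NULL, cfg, "wga", seed = 62))
  b <- aggregate_sites(simulate_reads(g, NULL, cfg, "wga", seed = 63))
  # same-base loci, as in the motif comparisons (adenine focal sites); a
  # cross-base mixture would couple the two replicates through the shared
  # per-base means and make the unpaired rank-sum conservative
  shared <- dplyr::inner_join(
    a[a$ref_base == "A", c("contig", "pos", "strand")],
    b[b$ref_base == "A", c("contig", "pos", "strand")],
    by = c("contig", "pos", "strand")
  )
  withr::with_seed(64, {
    ps <- replicate(200, {
      loci <- shared[sample.int(nrow(shared), 60), ]
      compare_native_wga(a, b, loci)$native_wga_p
    })
    folds <- replicate(50, {
      loci <- shared[sample.int(nrow(shared), 200), ]
      compare_native_wga(a, b, loci)$native_wga_fold
    })
  })
  expect_true(all(folds > 0.95 & folds < 1.05))
  # p-values roughly uniform under the null
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("k-mer focal tables enumerate contexts and rank planted ones first", {
  g <- generate_genome(30000, 0.5,
                       list(plant_spec("GA", 1, 150, 1,
                                       context = c("1" = 2))),
                       seed = 71)
  wga <- aggregate_sites(simulate_reads(g, g$planted, kinetics_config(),
                                        "wga", seed = 72))
  tab <- kmer_focal_table(wga, g$genome, k = 2, focal_index = 1,
                          focal_base = "A")
  expect_setequal(tab$kmer, c("AA", "CA", "GA", "TA"))
  expect_equal(tab$kmer[1], "GA")
  expect_gt(tab$mean_ipd[tab$kmer == "GA"],
            max(tab$mean_ipd[tab$kmer != "GA"]))
  # non-planted rows sit at the genome A mean
  null_means <- tab$mean_ipd[tab$kmer != "GA"]
  expect_equal(null_means / 1.38, rep(1, 3), tolerance = 0.03)
})
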