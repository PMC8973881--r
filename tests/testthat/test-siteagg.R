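test_that("MapQ formula matches its closed form and rejects bad domains", {
  expect_equal(mapq_from_error_prob(10^-12.7), 127)
  expect_equal(mapq_from_error_prob(1), 0)
  expect_equal(mapq_from_error_prob(0.01), 20)
  # round trip at representative scores
  for (q in c(0, 10, 127)) {
    expect_equal(mapq_from_error_prob(10^(-q / 10)), q)
  }
  expect_error(mapq_from_error_prob(0))
  expect_error(mapq_from_error_prob(1.5))
})

test_that("alignment filtering is strict at the threshold", {
  rec <- tibble::tibble(read_id = c("a", "b", "c"), mapq = c(126, 127, 128))
  expect_identical(filter_alignments(rec)$read_id, "c")
  expect_identical(nrow(filter_alignments(rec[0, ])), 0L)
  expect_identical(filter_alignments(rec, min_mapq = 0)$read_id,
                   c("a", "b", "c"))
  # derived from error probabilities when mapq is absent
  rec2 <- tibble::tibble(error_prob = c(1e-13, 1e-12))
  expect_equal(nrow(filter_alignments(rec2)), 1)
})

test_that("outlier trimming follows the log2 Tukey rule", {
  expect_identical(trim_outliers(c(1, 1, 1, 1)), c(1, 1, 1, 1))
  # interpolated quartiles of log2{0,0,0,0,~9.97} are 0; fences collapse
  expect_identical(trim_outliers(c(1, 1, 1, 1, 1000)), c(1, 1, 1, 1))
  expect_error(trim_outliers(numeric(0)), "empty")

  withr::with_seed(11, {
    for (i in 1:20) {
      x <- exp(rnorm(40, sd = runif(1, 0.1, 1)))
      out <- trim_outliers(x)
      # sub-multiset of the input
      expect_true(all(out %in% x))
      expect_lte(length(out), length(x))
      # re-trimming may shrink further but never grows
      expect_lte(length(trim_outliers(out)), length(out))
    }
  })
})

test_that("site aggregation applies validity, trimming and coverage rules", {
  # clean site: mean and count pass through
  s <- aggregate_sites(make_obs(rep(2, 30)))
  expect_equal(nrow(s), 1)
  expect_equal(s$mean_ipd, 2)
  expect_equal(s$valid_count, 30L)

  # neighbour mismatches drop the site below the threshold
  obs <- make_obs(rep(2, 30), neighbors_match = c(rep(FALSE, 10), rep(TRUE, 20)))
  s2 <- aggregate_sites(obs)
  expect_equal(nrow(s2), 0)
  expect_identical(attr(s2, "n_below_min"), 1L)

  # trimming happens before the coverage filter
  s3 <- aggregate_sites(make_obs(c(rep(2, 24), 200)))
  expect_equal(nrow(s3), 0)

  # reference N sites are excluded
  s4 <- aggregate_sites(make_obs(rep(2, 30), ref_base = "N"))
  expect_equal(nrow(s4), 0)

  # strands aggregate separately
  two <- dplyr::bind_rows(make_obs(rep(2, 30), strand = "+"),
                          make_obs(rep(4, 30), strand = "-"))
  s5 <- aggregate_sites(two)
  expect_equal(sort(s5$mean_ipd), c(2, 4))
})

test_that("one large outlier barely moves a trimmed site mean", {
  withr::with_seed(5, {
    clean <- 2 * exp(0.05 * rnorm(25))
  })
  contaminated <- c(clean[1:24], clean[25] * 50)
  m_clean <- mean(trim_outliers(clean))
  m_cont <- mean(trim_outliers(contaminated))
  expect_lt(abs(m_cont / m_clean - 1), 0.05)
})

test_that("genome base means are unweighted and report empty bases", {
  sites <- dplyr::bind_rows(
    make_sites(c(0, 1), c(1.0, 2.0), ref_base = "A"),
    make_sites(2, 0.8, ref_base = "C")
  )
  bm <- genome_base_means(sites)
  expect_equal(bm$mean_ipd[bm$ref_base == "A"], 1.5)
  expect_equal(bm$n_sites[bm$ref_base == "A"], 2L)
  expect_equal(bm$n_sites[bm$ref_base == "G"], 0L)
  expect_true(is.na(bm$mean_ipd[bm$ref_base == "G"]))
  # single site: mean is that site's mean
  expect_equal(genome_base_means(make_sites(0, 1.7))$mean_ipd[1], 1.7)
})

test_that("log2 histograms conserve and partition counts", {
  withr::with_seed(8, {
    sites <- dplyr::bind_rows(
      make_sites(1:50, exp(rnorm(50)), ref_base = "A"),
      make_sites(51:80, exp(rnorm(30)), ref_base = "T")
    )
  })
  h <- ipd_log2_histogram(sites, bin_width = 0.1)
  all_h <- h[h$base_label == "all", ]
  expect_equal(sum(all_h$count), nrow(sites))
  per_base <- tapply(h$count[h$base_label != "all"],
                     h$bin_left[h$base_label != "all"], sum)
  expect_equal(as.vector(per_base), all_h$count)

  h1 <- ipd_log2_histogram(make_sites(0, 2.0), bin_width = 0.1)
  hit <- h1[h1$base_label == "all" & h1$bin_left <= 1 & h1$bin_right > 1, ]
  expect_equal(hit$count, 1L)

  expect_error(ipd_log2_histogram(sites, bin_width = 0), "positive")
})

test_that("sites CSV dialect round-trips with 1-based tpl and 0/1 strand", {
  sites <- dplyr::bind_rows(
    make_sites(c(4, 9), c(1.25, 0.75), strand = "+"),
    make_sites(4, 2.5, strand = "-", ref_base = "T")
  )
  sites$ipd_sd <- c(0.2, 0.3, 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sites_csv(sites, path)
  lines <- readLines(path)
  expect_identical(lines[1], "refName,tpl,strand,base,tMean,tErr,coverage")
  expect_match(lines[2], "^\"c1\",5,0,A,")
  expect_match(lines[4], "^\"c1\",5,1,T,")
  back <- read_sites_csv(path)
  expect_equal(back$pos, sites$pos)
  expect_equal(back$strand, sites$strand)
  expect_equal(back$mean_ipd, sites$mean_ipd)
  expect_equal(back$valid_count, sites$valid_count)
  expect_equal(back$ipd_sd, sites$ipd_sd, tolerance = 1e-12)

  # optional modelPrediction column
  sites$predicted_ipd <- c(1.2, 0.8, 2.4)
  write_sites_csv(sites, path)
  expect_match(readLines(path)[1], "modelPrediction$")
  expect_equal(read_sites_csv(path)$predicted_ipd, sites$predicted_ipd)
})
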