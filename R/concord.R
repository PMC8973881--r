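# Concordance metrics on paired (observed, predicted) values.
# r is Pearson; p from the t transform; R^2 is the coefficient of
# determination of identity-line prediction (1 - SSres/SStot with the
# second argument as predictor); RMSE is on the working (log2) scale.
.concordance <- function(obs, pred) {
  n <- length(obs)
  stopifnot(n == length(pred))
  if (n < 3) stop("need at least 3 paired values", call. = FALSE)
  if (sd(obs) == 0 || sd(pred) == 0) {
    r <- NA_real_
    p <- NA_real_
  } else {
    ct <- cor.test(obs, pred, method = "pearson")
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  tibble(
    n = n, pearson_r = r, p_r = p,
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    rmse = sqrt(mean((obs - pred)^2))
  )
}

#' Correlation between two motif IPD profiles
#'
#' Pearson correlation of mean log2 IPDs over the motif positions plus
#' `include_upstream` upstream flank positions (upstream = 5' of the motif
#' on the motif strand; including the upstream flank adds the positions
#' that tend to carry extreme IPDs and makes the comparison more
#' reliable). Positions missing in either profile are dropped.
#'
#' @param profile_a,profile_b [motif_profile()] objects over the same
#'   motif length.
#' @param include_upstream Number of upstream flank positions included.
#'   Default 10.
#' @return One-row tibble of class `ipd_concordance`: `n`, `pearson_r`,
#'   `p_r`, `r2`, `rmse` (log2 scale).
#' @export
profile_correlation <- function(profile_a, profile_b, include_upstream = 10) {
  stopifnot(inherits(profile_a, "motif_profile"),
            inherits(profile_b, "motif_profile"))
  len_a <- nchar(attr(profile_a, "motif"))
  len_b <- nchar(attr(profile_b, "motif"))
  if (len_a != len_b) stop("profiles must share the motif length",
                           call. = FALSE)
  use <- function(p) {
    p[p$rel_pos >= -include_upstream & p$rel_pos < len_a & p$n_sites > 0,
      c("rel_pos", "mean_ipd")]
  }
  shared <- dplyr::inner_join(use(profile_a), use(profile_b),
                              by = "rel_pos", suffix = c("_a", "_b"))
  if (nrow(shared) < 3) {
    stop("fewer than 3 usable paired positions", call. = FALSE)
  }
  out <- .concordance(log2(shared$mean_ipd_a), log2(shared$mean_ipd_b))
  class(out) <- unique(c("ipd_concordance", class(out)))
  out
}

#' Observed versus model-predicted per-site IPDs
#'
#' Joins a predicted-IPD table (keyed by contig, position, strand — e.g.
#' the `modelPrediction` column of a kinetics CSV read with
#' [read_sites_csv()]) onto observed per-site kinetics and computes
#' Pearson r, its p-value, R^2 and RMSE on log2-transformed values, per
#' base identity (and pooled). Unmatched sites are skipped and counted in
#' the `n_unmatched` attribute.
#'
#' @param sites Observed `site_kinetics` tibble.
#' @param predicted Tibble with `contig`, `pos`, `strand` and
#'   `predicted_ipd` columns.
#' @param by_base Split by reference base. Default `TRUE`.
#' @return Tibble of class `ipd_concordance` with a `base` column
#'   (`"all"` plus one row per base when `by_base`).
#' @export
observed_vs_predicted <- function(sites, predicted, by_base = TRUE) {
  stopifnot(is.data.frame(sites), is.data.frame(predicted),
            "predicted_ipd" %in% names(predicted))
  key <- c("contig", "pos", "strand")
  shared <- dplyr::inner_join(
    dplyr::select(sites, dplyr::all_of(key), "ref_base", "mean_ipd"),
    dplyr::select(predicted, dplyr::all_of(key), "predicted_ipd"),
    by = key
  )
  if (nrow(shared) == 0) stop("no shared sites", call. = FALSE)
  groups <- if (by_base) c("all", sort(unique(shared$ref_base))) else "all"
  out <- purrr::map(groups, function(b) {
    sub <- if (b == "all") shared else shared[shared$ref_base == b, ]
    dplyr::bind_cols(tibble(base = b),
                     .concordance(log2(sub$mean_ipd),
                                  log2(sub$predicted_ipd)))
  }) |> dplyr::bind_rows()
  attr(out, "n_unmatched") <- nrow(sites) - nrow(shared)
  class(out) <- unique(c("ipd_concordance", class(out)))
  out
}

#' Replicate log2 IPD ratio as a function of minimum coverage
#'
#' For each minimum-coverage value `c` in the grid, restricts to sites
#' with `valid_count >= c` in *both* tables and summarises the per-site
#' `log2(IPD_B / IPD_A)` values. Site-level IPD estimates fluctuate
#' strongly between replicates at low coverage and converge as coverage
#' grows, so the spread should shrink along the grid.
#'
#' @param sites_a,sites_b `site_kinetics` tibbles of two replicates.
#' @param coverage_grid Increasing integer vector of minimum coverages.
#' @return Tibble of class `replicate_ratio`: `min_coverage`, `n`, `mean`,
#'   `sd`, `q25`, `median`, `q75` of the log2 ratios (`n = 0` rows carry
#'   `NA` summaries).
#' @export
replicate_ratio_by_coverage <- function(sites_a, sites_b,
                                        coverage_grid = c(5, 10, 15, 20, 25, 30)) {
  stopifnot(is.numeric(coverage_grid), !is.unsorted(coverage_grid))
  key <- c("contig", "pos", "strand")
  shared <- dplyr::inner_join(
    dplyr::select(sites_a, dplyr::all_of(key), va = "valid_count",
                  ia = "mean_ipd"),
    dplyr::select(sites_b, dplyr::all_of(key), vb = "valid_count",
                  ib = "mean_ipd"),
    by = key
  )
  if (nrow(shared[shared$va >= coverage_grid[1] &
                    shared$vb >= coverage_grid[1], ]) == 0) {
    stop("no shared sites at the smallest coverage-grid value",
         call. = FALSE)
  }
  out <- purrr::map(coverage_grid, function(cmin) {
    r <- log2(shared$ib / shared$ia)[shared$va >= cmin & shared$vb >= cmin]
    if (length(r) == 0) {
      tibble(min_coverage = cmin, n = 0L, mean = NA_real_, sd = NA_real_,
             q25 = NA_real_, median = NA_real_, q75 = NA_real_)
    } else {
      q <- quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
      tibble(min_coverage = cmin, n = length(r), mean = mean(r),
             sd = if (length(r) > 1) sd(r) else NA_real_,
             q25 = q[1], median = q[2], q75 = q[3])
    }
  }) |> dplyr::bind_rows()
  class(out) <- unique(c("replicate_ratio", class(out)))
  out
}
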