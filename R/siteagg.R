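#' Phred-scaled mapping quality from an error probability
#'
#' `MapQ(p) = -10 * log10(p)` where `p` is the probability that an alignment
#' is incorrect. Alignments with `p < 10^-12.7`, i.e. `MapQ > 127`, count as
#' high-confidence.
#'
#' @param p Numeric vector of incorrect-alignment probabilities in (0, 1].
#' @return Numeric vector of MapQ scores.
#' @export
#' @examples
#' mapq_from_error_prob(10^-12.7)  # 127
mapq_from_error_prob <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p must be in (0, 1]", call. = FALSE)
  }
  -10 * log10(p)
}

#' Filter alignment records by mapping quality
#'
#' Retains records with `mapq` strictly greater than `min_mapq` (the
#' high-quality rule is `MapQ > 127`, i.e. `p < 10^-12.7`). If the
#' table lacks a `mapq` column it is derived from `error_prob`.
#'
#' @param records Tibble with a `mapq` and/or `error_prob` column.
#' @param min_mapq Threshold; strict inequality. Default 127.
#' @return The retained rows.
#' @export
filter_alignments <- function(records, min_mapq = 127) {
  stopifnot(is.data.frame(records))
  if (!"mapq" %in% names(records)) {
    if (!"error_prob" %in% names(records)) {
      stop("records need a 'mapq' or 'error_prob' column", call. = FALSE)
    }
    records$mapq <- mapq_from_error_prob(records$error_prob)
  }
  dplyr::filter(records, .data$mapq > min_mapq)
}

# logical keep-mask of the log2-scale Tukey rule (interpolated quartiles)
.tukey_keep <- function(values, k = 1.5) {
  l <- log2(values)
  q <- quantile(l, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  l >= q[1] - k * iqr & l <= q[2] + k * iqr
}

#' Trim outlier IPDs at a locus
#'
#' Robust per-locus trimming applied before averaging. The default rule
#' keeps values whose log2 lies within the Tukey fences
#' `[Q1 - k*IQR, Q3 + k*IQR]` of the locus' log2 distribution, with
#' quartiles by linear interpolation on the sorted sample. The
#' `"percentile"` strategy instead drops values outside the central
#' `[trim_pct, 100 - trim_pct]` percentile band.
#'
#' @param values Positive numeric vector (nonempty).
#' @param k Tukey fence multiplier. Default 1.5.
#' @param method `"tukey_log2"` (default) or `"percentile"`.
#' @param trim_pct Percentile trimmed at each end for
#'   `method = "percentile"`. Default 1.
#' @return The retained values (a sub-multiset of the input).
#' @export
#' @examples
#' trim_outliers(c(1, 1, 1, 1, 1000))  # the 1000 is dropped
trim_outliers <- function(values, k = 1.5,
                          method = c("tukey_log2", "percentile"),
                          trim_pct = 1) {
  method <- match.arg(method)
  if (length(values) == 0) stop("empty input", call. = FALSE)
  stopifnot(is.numeric(values), all(values > 0))
  keep <- switch(method,
    tukey_log2 = .tukey_keep(values, k),
    percentile = {
      q <- quantile(values, c(trim_pct, 100 - trim_pct) / 100,
                    type = 7, names = FALSE)
      values >= q[1] & values <= q[2]
    }
  )
  values[keep]
}

#' Aggregate read-level IPD observations into per-site kinetics
#'
#' Per (contig, position, strand): observations whose neighbouring bases
#' mismatch the reference are dropped, outliers are trimmed
#' ([trim_outliers()], log2 Tukey rule), and the mean of the remaining
#' *valid* IPDs is taken. Sites at reference `N` are excluded. Only sites
#' with at least `min_valid` valid IPDs are emitted; the number of sites
#' dropped by the coverage filter is attached as attribute `n_below_min`.
#' Strands are kept separate (coverage is per strand).
#'
#' @param observations Tibble from [simulate_reads()] / [read_dataset()].
#' @param min_valid Minimum valid IPD count per site and strand. Default 25.
#' @param trim Apply outlier trimming. Default `TRUE`.
#' @param k Tukey fence multiplier passed to the trimming rule.
#' @return Tibble of class `site_kinetics`: `contig`, `pos`, `strand`,
#'   `ref_base`, `valid_count`, `mean_ipd`, `ipd_sd`.
#' @export
aggregate_sites <- function(observations, min_valid = 25, trim = TRUE,
                            k = 1.5) {
  stopifnot(is.data.frame(observations), min_valid >= 0)
  dt <- data.table::as.data.table(
    observations[observations$neighbors_match & observations$ref_base != "N",
                 c("contig", "pos", "strand", "ref_base", "ipd")]
  )
  if (nrow(dt) == 0) {
    out <- tibble(contig = character(), pos = integer(), strand = character(),
                  ref_base = character(), valid_count = integer(),
                  mean_ipd = numeric(), ipd_sd = numeric())
    attr(out, "n_below_min") <- 0L
    return(.as_site_kinetics(out))
  }
  agg <- dt[, {
    v <- ipd
    if (trim) v <- v[.tukey_keep(v, k)]
    list(valid_count = length(v), mean_ipd = mean(v),
         ipd_sd = if (length(v) > 1) sd(v) else 0)
  }, by = c("contig", "pos", "strand", "ref_base")]
  n_below <- sum(agg$valid_count < min_valid)
  agg <- agg[agg$valid_count >= min_valid, ]
  data.table::setorder(agg, contig, pos, strand)
  out <- as_tibble(agg)
  attr(out, "n_below_min") <- n_below
  .as_site_kinetics(out)
}

.as_site_kinetics <- function(x) {
  class(x) <- unique(c("site_kinetics", class(x)))
  x
}

#' Genome-wide per-base mean IPD
#'
#' Unweighted average of per-site mean IPDs grouped by reference base,
#' strands pooled. Bases without any site are reported with `n_sites = 0`
#' and `mean_ipd = NA`.
#'
#' @param sites A `site_kinetics` tibble.
#' @return Tibble with columns `ref_base`, `mean_ipd`, `n_sites`.
#' @export
genome_base_means <- function(sites) {
  stopifnot(is.data.frame(sites), nrow(sites) > 0)
  got <- sites |>
    dplyr::group_by(.data$ref_base) |>
    dplyr::summarise(mean_ipd = mean(.data$mean_ipd),
                     n_sites = dplyr::n(), .groups = "drop")
  tibble(ref_base = .BASES) |>
    dplyr::left_join(got, by = "ref_base") |>
    dplyr::mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L))
}

#' Histogram of per-site mean IPDs on the log2 scale
#'
#' Counts per-site mean IPDs in log2 bins of width `bin_width`, with bin
#' edges aligned to multiples of `bin_width`. When `by_base = TRUE` one
#' histogram per base is returned in addition to the pooled `"all"`
#' histogram, all on a common set of edges (so per-base counts partition
#' the pooled counts bin-wise).
#'
#' @param sites A `site_kinetics` tibble.
#' @param bin_width Positive bin width in log2 units. Default 0.1.
#' @param by_base Also return per-base histograms. Default `TRUE`.
#' @return Tibble of class `ipd_histogram`: `base_label`, `bin_left`,
#'   `bin_right` (log2 scale), `count`.
#' @export
ipd_log2_histogram <- function(sites, bin_width = 0.1, by_base = TRUE) {
  stopifnot(is.data.frame(sites), nrow(sites) > 0)
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be positive", call. = FALSE)
  }
  l <- log2(sites$mean_ipd)
  lo <- floor(min(l) / bin_width) * bin_width
  hi <- ceiling(max(l) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (max(l) >= edges[length(edges)]) edges <- c(edges, hi + bin_width)
  labels <- if (by_base) c("all", .BASES) else "all"
  out <- purrr::map(labels, function(lab) {
    v <- if (lab == "all") l else l[sites$ref_base == lab]
    cnt <- if (length(v)) {
      tabulate(findInterval(v, edges, rightmost.closed = FALSE),
               nbins = length(edges) - 1L)
    } else {
      integer(length(edges) - 1L)
    }
    tibble(base_label = lab, bin_left = edges[-length(edges)],
           bin_right = edges[-1], count = cnt)
  }) |> dplyr::bind_rows()
  class(out) <- unique(c("ipd_histogram", class(out)))
  out
}

#' Write per-site kinetics to CSV (kineticsTools-style dialect)
#'
#' Columns `refName,tpl,strand,base,tMean,tErr,coverage` with optional
#' `modelPrediction`. `tpl` is 1-based; `strand` is 0 for forward, 1 for
#' reverse; `refName` is quoted; `tErr` is the standard error of the
#' trimmed mean.
#'
#' @param sites A `site_kinetics` tibble (optionally with a
#'   `predicted_ipd` column, written as `modelPrediction`).
#' @param path Output path.
#' @export
write_sites_csv <- function(sites, path) {
  stopifnot(is.data.frame(sites))
  terr <- if ("ipd_sd" %in% names(sites)) {
    sites$ipd_sd / sqrt(pmax(sites$valid_count, 1L))
  } else {
    rep(0, nrow(sites))
  }
  has_pred <- "predicted_ipd" %in% names(sites)
  header <- paste(c("refName", "tpl", "strand", "base", "tMean", "tErr",
                    "coverage", if (has_pred) "modelPrediction"),
                  collapse = ",")
  body <- sprintf("\"%s\",%d,%d,%s,%.17g,%.17g,%d",
                  sites$contig, sites$pos + 1L,
                  ifelse(sites$strand == "+", 0L, 1L),
                  sites$ref_base, sites$mean_ipd, terr, sites$valid_count)
  if (has_pred) body <- sprintf("%s,%.17g", body, sites$predicted_ipd)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a per-site kinetics CSV written by [write_sites_csv()]
#' @param path CSV path.
#' @return A `site_kinetics` tibble (with `predicted_ipd` if the file has a
#'   `modelPrediction` column).
#' @export
read_sites_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble(
    contig = as.character(raw$refName),
    pos = as.integer(raw$tpl) - 1L,
    strand = ifelse(raw$strand == 0L, "+", "-"),
    ref_base = as.character(raw$base),
    valid_count = as.integer(raw$coverage),
    mean_ipd = as.numeric(raw$tMean),
    ipd_sd = as.numeric(raw$tErr) * sqrt(pmax(as.integer(raw$coverage), 1L))
  )
  if ("modelPrediction" %in% names(raw)) {
    out$predicted_ipd <- as.numeric(raw$modelPrediction)
  }
  .as_site_kinetics(out)
}
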