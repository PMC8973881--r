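#' Read genomic regions from a BED file
#'
#' @param path BED path.
#' @param label Region label; defaults to the BED `name` column when
#'   present, otherwise the file name.
#' @return Tibble `label`, `contig`, `start`, `end` (0-based half-open).
#' @export
read_regions_bed <- function(path, label = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  lab <- if (!is.null(label)) {
    rep(label, length(gr))
  } else if (!is.null(gr$name) && !all(is.na(gr$name))) {
    as.character(gr$name)
  } else {
    rep(tools::file_path_sans_ext(basename(path)), length(gr))
  }
  tibble(label = lab,
         contig = as.character(GenomicRanges::seqnames(gr)),
         start = BiocGenerics::start(gr) - 1L,
         end = BiocGenerics::end(gr))
}

#' Read genomic regions from a GFF3 file
#'
#' GFF3 coordinates (1-based closed) are converted to 0-based half-open.
#'
#' @param path GFF3 path.
#' @param label_map Optional named character mapping from GFF3 `type` to a
#'   region label; unmapped types keep their type name.
#' @return Tibble `label`, `contig`, `start`, `end`.
#' @export
read_regions_gff3 <- function(path, label_map = NULL) {
  gr <- rtracklayer::import(path, format = "GFF3")
  lab <- as.character(gr$type)
  if (!is.null(label_map)) {
    hit <- lab %in% names(label_map)
    lab[hit] <- unname(label_map[lab[hit]])
  }
  tibble(label = lab,
         contig = as.character(GenomicRanges::seqnames(gr)),
         start = BiocGenerics::start(gr) - 1L,
         end = BiocGenerics::end(gr))
}

.regions_granges <- function(regions) {
  GenomicRanges::GRanges(
    regions$contig,
    IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

.sites_granges <- function(contig, pos) {
  GenomicRanges::GRanges(contig, IRanges::IRanges(pos + 1L, pos + 1L))
}

#' Genomic-feature enrichment of extreme-IPD loci
#'
#' For each region label and locus class, the fraction of eligible bases in
#' the region that carry a kinetic-feature locus is compared with the
#' genome-wide fraction: `fold_change = (k/n) / p0` where `n` is the number
#' of eligible site records (coverage-filtered, per strand) overlapping the
#' label's intervals, `k` the number of class loci among them, and `p0` the
#' genome-wide class fraction. Significance is the two-sided binomial test
#' (minimum-likelihood two-sided p of `Binomial(n, p0)`); `q` is a
#' Benjamini-Hochberg adjustment across labels within each class. High and
#' low loci are tested separately. Intervals sharing a label are unioned
#' first; overlapping *labels* count independently.
#'
#' @param loci An `extreme_loci` object or tibble with `contig`, `pos`,
#'   `strand`, `class`.
#' @param regions Region tibble (`label`, `contig`, `start`, `end`), e.g.
#'   from [read_regions_bed()] / [read_regions_gff3()].
#' @param eligible_sites `site_kinetics` tibble of all eligible
#'   (coverage-filtered) sites.
#' @return Tibble of class `ipd_enrichment`: `label`, `class`, `n_trials`,
#'   `k_successes`, `p0`, `fold_change`, `p_binomial`, `q_adjusted`,
#'   `testable`.
#' @export
region_enrichment <- function(loci, regions, eligible_sites) {
  if (inherits(loci, "extreme_loci")) loci <- loci$loci
  stopifnot(is.data.frame(loci), is.data.frame(regions),
            is.data.frame(eligible_sites))
  elig_gr <- .sites_granges(eligible_sites$contig, eligible_sites$pos)
  loci_gr <- .sites_granges(loci$contig, loci$pos)
  n_elig_total <- nrow(eligible_sites)

  out <- list()
  for (cls in sort(unique(loci$class))) {
    in_cls <- loci$class == cls
    p0 <- sum(in_cls) / n_elig_total
    for (lab in unique(regions$label)) {
      rg <- GenomicRanges::reduce(
        .regions_granges(regions[regions$label == lab, ])
      )
      n <- sum(IRanges::overlapsAny(elig_gr, rg))
      k <- sum(IRanges::overlapsAny(loci_gr[in_cls], rg))
      testable <- n > 0 && p0 > 0
      out[[length(out) + 1L]] <- tibble(
        label = lab, class = cls, n_trials = n, k_successes = k, p0 = p0,
        fold_change = if (testable) (k / n) / p0 else NA_real_,
        p_binomial = if (testable) binom.test(k, n, p0)$p.value else NA_real_,
        testable = testable
      )
    }
  }
  res <- dplyr::bind_rows(out) |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(q_adjusted = p.adjust(.data$p_binomial, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::relocate("q_adjusted", .after = "p_binomial")
  class(res) <- unique(c("ipd_enrichment", class(res)))
  res
}

#' Correlation of enrichment fold changes across samples
#'
#' Pearson correlation over the log2 fold changes of labels shared between
#' two enrichment result sets (matched on label and class), with the
#' p-value from the t transform on n - 2 degrees of freedom.
#'
#' @param results_a,results_b Tibbles from [region_enrichment()].
#' @return One-row tibble: `n`, `pearson_r`, `p_value`.
#' @export
fold_change_correlation <- function(results_a, results_b) {
  shared <- dplyr::inner_join(
    dplyr::filter(results_a, .data$testable, .data$fold_change > 0),
    dplyr::filter(results_b, .data$testable, .data$fold_change > 0),
    by = c("label", "class"), suffix = c("_a", "_b")
  )
  if (nrow(shared) < 3) {
    stop("need at least 3 shared testable labels", call. = FALSE)
  }
  ct <- cor.test(log2(shared$fold_change_a), log2(shared$fold_change_b),
                 method = "pearson")
  tibble(n = nrow(shared), pearson_r = unname(ct$estimate),
         p_value = ct$p.value)
}
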