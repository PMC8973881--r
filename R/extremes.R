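#' Detect loci with extreme (top/bottom percentile) IPDs
#'
#' Thresholds are computed over the pooled per-site mean IPD distribution
#' (all bases, both strands) by the nearest-rank rule: with
#' `k = ceiling((1 - pct/100) * N)`, the high threshold is the k-th
#' smallest site mean and high loci are those *strictly* above it (low loci
#' symmetrically below the k-th largest). Under tie-free data exactly
#' `floor(pct/100 * N)` loci are flagged on each side; ties are never
#' flagged.
#'
#' @param sites A `site_kinetics` tibble (already coverage-filtered).
#' @param pct Percentage flagged at each extreme, in (0, 50). Default 1.
#' @return A list of class `extreme_loci`: `pct`, `hi_threshold`,
#'   `lo_threshold`, `n_sites`, and `loci`, a tibble with columns `contig`,
#'   `pos`, `strand`, `class` (`"high"`/`"low"`), `mean_ipd`, `ref_base`.
#' @export
detect_extreme_loci <- function(sites, pct = 1.0) {
  stopifnot(is.data.frame(sites))
  if (nrow(sites) == 0) stop("no sites", call. = FALSE)
  if (!is.numeric(pct) || pct <= 0 || pct >= 50) {
    stop("pct must be in (0, 50)", call. = FALSE)
  }
  v <- sort(sites$mean_ipd)
  n <- length(v)
  k <- ceiling((1 - pct / 100) * n)
  hi <- v[k]
  lo <- v[n - k + 1L]
  cls <- rep(NA_character_, nrow(sites))
  cls[sites$mean_ipd > hi] <- "high"
  cls[sites$mean_ipd < lo] <- "low"
  loci <- sites[!is.na(cls), c("contig", "pos", "strand", "ref_base",
                               "mean_ipd")]
  loci$class <- cls[!is.na(cls)]
  loci <- as_tibble(loci)[, c("contig", "pos", "strand", "class",
                              "mean_ipd", "ref_base")]
  structure(
    list(pct = pct, hi_threshold = hi, lo_threshold = lo, n_sites = n,
         loci = loci),
    class = "extreme_loci"
  )
}

#' @export
print.extreme_loci <- function(x, ...) {
  cat("Extreme-IPD loci (", x$pct, "% each tail of ", x$n_sites,
      " sites)\n", sep = "")
  cat("  high: ", sum(x$loci$class == "high"), " loci above ",
      signif(x$hi_threshold, 4), "\n", sep = "")
  cat("  low:  ", sum(x$loci$class == "low"), " loci below ",
      signif(x$lo_threshold, 4), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.extreme_loci <- function(x, ...) x$loci

#' @exportS3Method generics::glance
glance.extreme_loci <- function(x, ...) {
  tibble(pct = x$pct, n_sites = x$n_sites,
         hi_threshold = x$hi_threshold, lo_threshold = x$lo_threshold,
         n_high = sum(x$loci$class == "high"),
         n_low = sum(x$loci$class == "low"))
}

#' Export sequence windows around loci for motif discovery
#'
#' One record per locus, centred on the locus and clipped at contig ends
#' (clipped records are flagged in the FASTA description). Minus-strand
#' loci emit the reverse complement, so the focal base is always read in
#' its own strand's orientation. Record ids encode
#' `contig:pos:strand:class` (0-based pos).
#'
#' @param loci An `extreme_loci` object or a tibble with `contig`, `pos`,
#'   `strand` and optionally `class` columns.
#' @param genome See [as_genome()].
#' @param width Odd window width in bp. Default 41.
#' @param path Optional FASTA output path.
#' @return A [Biostrings::DNAStringSet] (invisibly if `path` is given).
#' @export
export_windows <- function(loci, genome, width = 41, path = NULL) {
  if (inherits(loci, "extreme_loci")) loci <- loci$loci
  genome <- as_genome(genome)
  if (!.is_count(width) || width %% 2 == 0) {
    stop("width must be an odd integer (the centre base must be defined)",
         call. = FALSE)
  }
  half <- (width - 1L) / 2L
  lens <- setNames(Biostrings::width(genome), names(genome))
  cls <- if ("class" %in% names(loci)) loci$class else rep("locus", nrow(loci))
  st <- pmax(loci$pos - half, 0L)
  en <- pmin(loci$pos + half, lens[loci$contig] - 1L)  # inclusive
  clipped <- (en - st + 1L) < width
  seqs <- character(nrow(loci))
  for (nm in unique(loci$contig)) {
    sel <- which(loci$contig == nm)
    seqs[sel] <- substring(as.character(genome[[nm]]), st[sel] + 1L,
                           en[sel] + 1L)
  }
  minus <- loci$strand == "-"
  if (any(minus)) seqs[minus] <- .revcomp_chr(seqs[minus])
  ids <- sprintf("%s:%d:%s:%s%s", loci$contig, loci$pos, loci$strand, cls,
                 ifelse(clipped, " clipped", ""))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  if (!is.null(path)) {
    Biostrings::writeXStringSet(out, path, width = 60L)
    return(invisible(out))
  }
  out
}

#' Write extreme loci to BED
#'
#' 0-based half-open intervals; `name` is the locus class and `score` is
#' `round(1000 * log2(mean IPD))`.
#'
#' @param loci An `extreme_loci` object or its `loci` tibble.
#' @param path Output path.
#' @export
write_loci_bed <- function(loci, path) {
  if (inherits(loci, "extreme_loci")) loci <- loci$loci
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   loci$contig, loci$pos, loci$pos + 1L, loci$class,
                   round(1000 * log2(loci$mean_ipd)), loci$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a motif-list text file
#'
#' One IUPAC string per line, optionally followed by whitespace and a
#' 1-based focal position; `#` starts a comment. Focal positions are
#' converted to 0-based offsets (`NA` when absent).
#'
#' @param path Text file path.
#' @return Tibble `motif`, `focal_offset` (0-based).
#' @export
read_motif_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  out <- tibble(
    motif = vapply(parts, `[[`, character(1), 1L),
    focal_offset = vapply(parts, function(p) {
      if (length(p) >= 2) as.integer(p[[2]]) - 1L else NA_integer_
    }, integer(1))
  )
  purrr::walk(out$motif, .check_iupac)
  out
}

#' Test motif positions for significantly extreme IPDs
#'
#' For every motif position (and, at degenerate positions, every resolved
#' base) the per-occurrence site IPDs are compared against the genome-wide
#' same-base site IPDs with a two-sided Wilcoxon rank-sum test; raw
#' p-values are Bonferroni-multiplied by `n_tests` and capped at 1.
#'
#' @param profile A [motif_profile()].
#' @param sites The `site_kinetics` table supplying the genome-wide
#'   baseline.
#' @param n_tests Bonferroni family size; defaults to the number of
#'   profile positions (motif length + 2 * flank). Must be at least the
#'   number of positions tested.
#' @param alpha Significance level applied to the adjusted p-values.
#'   Default 0.05.
#' @return Tibble: `rel_pos`, `ref_base`, `n_sites`, `p_raw`,
#'   `p_adjusted`, `significant`. Positions without data get `NA`
#'   p-values.
#' @export
test_motif_extremeness <- function(profile, sites, n_tests = NULL,
                                   alpha = 0.05) {
  stopifnot(inherits(profile, "motif_profile"))
  sv <- attr(profile, "site_values")
  if (is.null(n_tests)) n_tests <- nrow(profile)
  if (n_tests < length(unique(sv$rel_pos))) {
    stop("n_tests must be at least the number of positions tested",
         call. = FALSE)
  }
  tested <- sv |>
    dplyr::group_by(.data$rel_pos, .data$ref_base) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      p_raw = wilcoxon_ranksum(
        .data$mean_ipd,
        sites$mean_ipd[sites$ref_base == .data$ref_base[1]]
      )$p_value,
      .groups = "drop"
    )
  out <- tibble(rel_pos = profile$rel_pos) |>
    dplyr::left_join(tested, by = "rel_pos") |>
    dplyr::mutate(
      p_adjusted = pmin(1, .data$p_raw * n_tests),
      significant = !is.na(.data$p_adjusted) & .data$p_adjusted < alpha
    )
  out
}
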