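#' Scan a genome for occurrences of an IUPAC motif
#'
#' Every window matching the degenerate pattern on the plus strand is
#' reported with strand `+`; every window whose reverse complement matches
#' is reported with strand `-` (a palindromic motif such as GATC therefore
#' yields both strands at the same start). Overlapping matches are all
#' reported.
#'
#' @param genome See [as_genome()].
#' @param motif IUPAC string.
#' @return Tibble with columns `contig`, `start` (0-based plus-strand
#'   offset of the window), `strand`.
#' @export
#' @examples
#' scan_motif(c(chr = "GGATCC"), "GATC")
scan_motif <- function(genome, motif) {
  genome <- as_genome(genome)
  .check_iupac(motif)
  scan_one <- function(pattern, strand) {
    hits <- Biostrings::vmatchPattern(Biostrings::DNAString(pattern), genome,
                                      fixed = FALSE)
    purrr::map2(names(genome), as.list(hits), function(nm, ir) {
      if (length(ir) == 0) return(NULL)
      tibble(contig = nm, start = BiocGenerics::start(ir) - 1L,
             strand = strand)
    }) |> dplyr::bind_rows()
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  out <- dplyr::bind_rows(scan_one(motif, "+"), scan_one(rc, "-"))
  if (nrow(out) == 0) {
    return(tibble(contig = character(), start = integer(),
                  strand = character()))
  }
  dplyr::arrange(out, .data$contig, .data$start, .data$strand)
}

#' Per-position IPD profile of a motif with flanking positions
#'
#' For each occurrence, relative positions are read 5'-to-3' along the
#' motif strand (position 0 = first motif base; negative = upstream flank).
#' The IPD used at a relative position is the per-site mean on that same
#' strand; sites removed by the coverage filter simply do not contribute.
#' Occurrences whose flanks run off the contig are kept — out-of-range
#' positions contribute nothing.
#'
#' @param sites A `site_kinetics` tibble.
#' @param occurrences Tibble from [scan_motif()].
#' @param motif The scanned IUPAC motif (needed for its length).
#' @param flank Number of flanking positions on each side. Default 10.
#' @return A tibble of class `motif_profile` with columns `rel_pos`,
#'   `mean_ipd`, `se` (standard error; 0 when `n_sites = 1`), `n_sites`,
#'   and attributes `motif`, `flank`, `n_occurrences` and `site_values`
#'   (per-position site-level values used downstream).
#' @export
motif_profile <- function(sites, occurrences, motif, flank = 10) {
  .check_iupac(motif)
  stopifnot(is.data.frame(sites), is.data.frame(occurrences),
            .is_count(flank), flank >= 0)
  len <- nchar(motif)
  rel <- seq.int(-flank, len + flank - 1L)
  if (nrow(occurrences) == 0) stop("no motif occurrences", call. = FALSE)

  grid <- tidyr::crossing(dplyr::mutate(occurrences, .occ = dplyr::row_number()),
                          rel_pos = rel) |>
    dplyr::mutate(pos = ifelse(.data$strand == "+",
                               .data$start + .data$rel_pos,
                               .data$start + len - 1L - .data$rel_pos))
  joined <- dplyr::inner_join(
    grid,
    dplyr::select(sites, "contig", "pos", "strand", "ref_base", "mean_ipd"),
    by = c("contig", "pos", "strand")
  )
  if (nrow(joined) == 0) {
    stop("no usable sites at any motif position (coverage-filtered?)",
         call. = FALSE)
  }
  prof <- tibble(rel_pos = rel) |>
    dplyr::left_join(
      joined |>
        dplyr::group_by(.data$rel_pos) |>
        dplyr::summarise(
          mean_ipd = mean(.data$mean_ipd),
          se = if (dplyr::n() > 1) sd(.data$mean_ipd) / sqrt(dplyr::n()) else 0,
          n_sites = dplyr::n(), .groups = "drop"
        ),
      by = "rel_pos"
    ) |>
    dplyr::mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L))
  attr(prof, "motif") <- motif
  attr(prof, "flank") <- as.integer(flank)
  attr(prof, "n_occurrences") <- nrow(occurrences)
  attr(prof, "site_values") <-
    dplyr::select(joined, "rel_pos", "ref_base", "mean_ipd")
  class(prof) <- unique(c("motif_profile", class(prof)))
  prof
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Reports the rank-sum statistic of `x` (midranks for ties) and a
#' two-sided p-value: exact by enumeration when the smaller sample has at
#' most `exact_max` observations and there are no ties, otherwise a normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y Nonempty numeric vectors.
#' @param exact Force (`TRUE`/`FALSE`) or auto-select (`NULL`, default) the
#'   exact path.
#' @param exact_max Largest smaller-sample size for the automatic exact
#'   path. Default 8.
#' @return One-row tibble: `statistic` (rank-sum of `x`), `p_value`,
#'   `exact`.
#' @export
#' @examples
#' wilcoxon_ranksum(c(1, 2), c(3, 4))  # exact p = 1/3
wilcoxon_ranksum <- function(x, y, exact = NULL, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- min(length(x), length(y)) <= exact_max && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  w <- unname(ht$statistic) + length(x) * (length(x) + 1) / 2
  tibble(statistic = w, p_value = min(1, ht$p.value),
         exact = exact && !ties)
}

#' Ratio of increase of a motif's focal nucleotide
#'
#' The ratio of increase is the mean IPD of the focal nucleotide over all
#' motif occurrences divided by the genome-wide mean IPD *of that same
#' base*. Significance is a Wilcoxon rank-sum test of the focal-site IPDs
#' against all genome-wide same-base site IPDs. At degenerate focal
#' positions each resolved base is reported separately, plus a pooled row
#' (compared against the union of the resolved bases' genome-wide
#' distributions).
#'
#' @param profile A [motif_profile()].
#' @param sites The `site_kinetics` table the profile was computed from
#'   (supplies the genome-wide baseline).
#' @param focal_offset 0-based offset of the focal base within the motif.
#' @return Tibble of class `ipd_comparison`: `focal_base`, `n_sites`,
#'   `mean_ipd_motif`, `mean_ipd_genome`, `ratio_of_increase`, `ranksum_p`.
#' @export
ratio_of_increase <- function(profile, sites, focal_offset) {
  stopifnot(inherits(profile, "motif_profile"))
  sv <- attr(profile, "site_values")
  focal <- sv[sv$rel_pos == focal_offset, ]
  if (nrow(focal) == 0) stop("no focal-site IPDs at offset ", focal_offset,
                             call. = FALSE)
  one <- function(vals, bases, label) {
    genome_vals <- sites$mean_ipd[sites$ref_base %in% bases]
    if (length(genome_vals) == 0) {
      stop("no genome-wide sites for base ", paste(bases, collapse = "/"),
           call. = FALSE)
    }
    wt <- wilcoxon_ranksum(vals, genome_vals)
    tibble(focal_base = label, n_sites = length(vals),
           mean_ipd_motif = mean(vals),
           mean_ipd_genome = mean(genome_vals),
           ratio_of_increase = mean(vals) / mean(genome_vals),
           ranksum_p = wt$p_value)
  }
  bases <- sort(unique(focal$ref_base))
  out <- purrr::map(bases, function(b) {
    one(focal$mean_ipd[focal$ref_base == b], b, b)
  }) |> dplyr::bind_rows()
  if (length(bases) > 1) {
    out <- dplyr::bind_rows(out, one(focal$mean_ipd, bases, "pooled"))
  }
  class(out) <- unique(c("ipd_comparison", class(out)))
  out
}

#' Compare native and WGA IPDs at a set of loci
#'
#' The modification signal of a locus set is the fold
#' `mean(native IPD) / mean(WGA IPD)` over the shared loci, with a
#' two-sided Wilcoxon rank-sum p-value comparing the two per-site mean
#' collections. Loci come either from motif-scan focal positions or from an
#' explicit list (e.g. previously called modified sites). Loci missing from
#' either table (coverage-filtered) are skipped and counted.
#'
#' @param native_sites,wga_sites `site_kinetics` tibbles.
#' @param loci Tibble with columns `contig`, `pos`, `strand` (see
#'   [planted_loci()], [focal_loci()]).
#' @return One-row tibble of class `ipd_comparison`: `n_loci`,
#'   `n_skipped`, `mean_native`, `mean_wga`, `native_wga_fold`,
#'   `native_wga_p`.
#' @export
compare_native_wga <- function(native_sites, wga_sites, loci) {
  stopifnot(is.data.frame(loci),
            all(c("contig", "pos", "strand") %in% names(loci)))
  key <- c("contig", "pos", "strand")
  nat <- dplyr::inner_join(loci, dplyr::select(native_sites,
                                               dplyr::all_of(c(key, "mean_ipd"))),
                           by = key)
  wga <- dplyr::inner_join(loci, dplyr::select(wga_sites,
                                               dplyr::all_of(c(key, "mean_ipd"))),
                           by = key)
  shared <- dplyr::inner_join(nat, wga, by = key,
                              suffix = c("_native", "_wga"))
  if (nrow(shared) == 0) {
    stop("no loci shared between the native and WGA site tables",
         call. = FALSE)
  }
  wt <- wilcoxon_ranksum(shared$mean_ipd_native, shared$mean_ipd_wga)
  out <- tibble(
    n_loci = nrow(shared), n_skipped = nrow(loci) - nrow(shared),
    mean_native = mean(shared$mean_ipd_native),
    mean_wga = mean(shared$mean_ipd_wga),
    native_wga_fold = mean(shared$mean_ipd_native) / mean(shared$mean_ipd_wga),
    native_wga_p = wt$p_value
  )
  class(out) <- unique(c("ipd_comparison", class(out)))
  out
}

#' Focal loci of motif occurrences
#' @param occurrences Tibble from [scan_motif()].
#' @param motif The scanned motif.
#' @param focal_offset 0-based focal offset within the motif.
#' @return Tibble `contig`, `pos`, `strand` of the focal base of every
#'   occurrence.
#' @export
focal_loci <- function(occurrences, motif, focal_offset) {
  len <- nchar(motif)
  stopifnot(focal_offset >= 0, focal_offset < len)
  tibble(
    contig = occurrences$contig,
    pos = as.integer(ifelse(occurrences$strand == "+",
                            occurrences$start + focal_offset,
                            occurrences$start + len - 1L - focal_offset)),
    strand = occurrences$strand
  )
}

#' Mean focal-base IPD for every k-mer context
#'
#' Enumerates all k-mers over ACGT with the required base at
#' `focal_index` and reports the unweighted mean of per-site mean IPDs of
#' sites whose k-mer context (read 5'-to-3' on the site's strand) matches.
#' Both strands contribute, as in [motif_profile()]. Absent k-mers are
#' reported with `n_sites = 0`.
#'
#' @param sites A `site_kinetics` tibble.
#' @param genome See [as_genome()].
#' @param k k-mer length.
#' @param focal_index 0-based offset of the focal base within the k-mer.
#' @param focal_base The required focal base (`"A"`, `"C"`, `"G"` or
#'   `"T"`).
#' @return Tibble `kmer`, `mean_ipd`, `n_sites`, sorted by decreasing
#'   `mean_ipd`.
#' @export
kmer_focal_table <- function(sites, genome, k, focal_index, focal_base) {
  genome <- as_genome(genome)
  stopifnot(.is_count(k), k >= 1, .is_count(focal_index),
            focal_index >= 0, focal_index < k,
            focal_base %in% .BASES)
  seqs <- setNames(as.character(genome), names(genome))
  focal <- sites[sites$ref_base == focal_base, ]
  kmers <- character(nrow(focal))
  ok <- logical(nrow(focal))
  for (nm in unique(focal$contig)) {
    s <- seqs[[nm]]
    L <- nchar(s)
    sel <- which(focal$contig == nm)
    pos <- focal$pos[sel]
    plus <- focal$strand[sel] == "+"
    # plus strand: window starts at pos - focal_index
    st <- ifelse(plus, pos - focal_index, pos - (k - 1L - focal_index))
    en <- st + k - 1L
    inb <- st >= 0 & en < L
    sub <- substring(s, st + 1L, en + 1L)
    sub[plus == FALSE & inb] <- .revcomp_chr(sub[plus == FALSE & inb])
    kmers[sel] <- sub
    ok[sel] <- inb
  }
  focal <- focal[ok, , drop = FALSE]
  km <- kmers[ok]
  keep <- !grepl("N", km)
  focal <- focal[keep, , drop = FALSE]
  km <- km[keep]
  got <- tibble(kmer = km, mean_ipd = focal$mean_ipd) |>
    dplyr::group_by(.data$kmer) |>
    dplyr::summarise(mean_ipd = mean(.data$mean_ipd),
                     n_sites = dplyr::n(), .groups = "drop")
  all_kmers <- do.call(
    tidyr::crossing,
    setNames(lapply(seq_len(k), function(i) {
      if (i == focal_index + 1L) focal_base else .BASES
    }), paste0("p", seq_len(k)))
  )
  all_kmers <- tibble(kmer = do.call(paste0, all_kmers))
  all_kmers |>
    dplyr::left_join(got, by = "kmer") |>
    dplyr::mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L)) |>
    dplyr::arrange(dplyr::desc(.data$mean_ipd))
}
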