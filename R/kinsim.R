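#' Kinetics model configuration
#'
#' Parameters of the generative model for per-pulse interpulse durations
#' (IPDs). Each observed IPD at a site is
#' `mu_base * c_ctx * f_mod * exp(sigma * Z - sigma^2 / 2)` with `Z` standard
#' normal, so that the *arithmetic* mean of the observations equals the
#' product of the configured multipliers. With probability `outlier_prob` an
#' observation is further multiplied by `outlier_scale` (rare stalled-pulse
#' events); with probability `neighbor_mismatch_prob` the observation is
#' marked as having mismatched neighbouring bases and is therefore invalid
#' for aggregation.
#'
#' @param base_mean_ipd Named positive numeric, arithmetic mean IPD per
#'   template base (dimensionless). Defaults `A = 1.38`, `C = 0.95`,
#'   `G = 1.00`, `T = 0.65` — the per-base genome averages observed on a
#'   whole-genome-amplified *C. elegans* sample.
#' @param log_sigma Non-negative standard deviation of the natural-log IPD
#'   (per-pulse dispersion). Default 0.4.
#' @param coverage_per_strand Positive Poisson mean of the per-site,
#'   per-strand observation count. Default 30.
#' @param outlier_prob Probability in `[0, 1)` that a pulse is a large
#'   outlier. Default 0.001.
#' @param outlier_scale Multiplier (> 1) applied to outlier pulses.
#'   Default 50.
#' @param neighbor_mismatch_prob Probability in `[0, 1)` that an observation
#'   has mismatched neighbours. Default 0.01.
#'
#' @return A list of class `kinetics_config`.
#' @export
#' @examples
#' cfg <- kinetics_config(log_sigma = 0)
#' cfg$base_mean_ipd
kinetics_config <- function(base_mean_ipd = c(A = 1.38, C = 0.95, G = 1.00, T = 0.65),
                            log_sigma = 0.4,
                            coverage_per_strand = 30,
                            outlier_prob = 0.001,
                            outlier_scale = 50,
                            neighbor_mismatch_prob = 0.01) {
  stopifnot(
    is.numeric(base_mean_ipd), all(.BASES %in% names(base_mean_ipd)),
    all(base_mean_ipd > 0),
    is.numeric(log_sigma), length(log_sigma) == 1L, log_sigma >= 0,
    is.numeric(coverage_per_strand), coverage_per_strand > 0,
    is.numeric(outlier_prob), outlier_prob >= 0, outlier_prob < 1,
    is.numeric(outlier_scale), outlier_scale > 1,
    is.numeric(neighbor_mismatch_prob), neighbor_mismatch_prob >= 0,
    neighbor_mismatch_prob < 1
  )
  structure(
    list(
      base_mean_ipd = base_mean_ipd[.BASES],
      log_sigma = log_sigma,
      coverage_per_strand = coverage_per_strand,
      outlier_prob = outlier_prob,
      outlier_scale = outlier_scale,
      neighbor_mismatch_prob = neighbor_mismatch_prob
    ),
    class = "kinetics_config"
  )
}

#' Specify a motif to plant in a synthetic genome
#'
#' @param motif IUPAC string (e.g. `"GATC"`, `"GGNGGNGGNGGN"`).
#' @param focal_offset 0-based offset of the focal (e.g. modified) base
#'   within the motif.
#' @param count Number of non-overlapping occurrences to plant.
#' @param mod_multiplier Modification multiplier applied to the focal base's
#'   IPD in `native` mode only (1 = unmodified).
#' @param context Optional named numeric of sequence-context multipliers;
#'   names are relative offsets (0-based within the motif; negative values
#'   address positions upstream of the motif). Applied in both modes.
#' @param strand Strand the motif is written on, `"+"` or `"-"`. A
#'   minus-strand plant inserts the reverse complement into the plus-strand
#'   sequence.
#'
#' @return A list of class `plant_spec`.
#' @export
#' @examples
#' plant_spec("GATC", focal_offset = 1, count = 5, mod_multiplier = 8.57)
plant_spec <- function(motif, focal_offset, count,
                       mod_multiplier = 1, context = NULL, strand = "+") {
  .check_iupac(motif)
  stopifnot(
    .is_count(focal_offset), focal_offset >= 0, focal_offset < nchar(motif),
    .is_count(count), count >= 1,
    is.numeric(mod_multiplier), mod_multiplier > 0,
    strand %in% c("+", "-")
  )
  if (!is.null(context)) {
    stopifnot(is.numeric(context), all(context > 0), !is.null(names(context)),
              !anyNA(suppressWarnings(as.integer(names(context)))))
  }
  structure(
    list(motif = motif, focal_offset = as.integer(focal_offset),
         count = as.integer(count), mod_multiplier = mod_multiplier,
         context = context, strand = strand),
    class = "plant_spec"
  )
}

.check_iupac <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1L, nzchar(motif))
  chars <- strsplit(motif, "")[[1]]
  bad <- setdiff(chars, names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad) > 0) {
    stop("invalid IUPAC character(s) in motif '", motif, "': ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  invisible(motif)
}

# resolve degenerate IUPAC positions uniformly among allowed bases
.resolve_iupac <- function(motif) {
  chars <- strsplit(motif, "")[[1]]
  resolved <- vapply(chars, function(ch) {
    allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]]
    if (length(allowed) == 1L) allowed else sample(allowed, 1L)
  }, character(1))
  paste0(resolved, collapse = "")
}

#' Generate a synthetic reference genome with planted motif sites
#'
#' Background bases are i.i.d. with `P(G) = P(C) = gc_fraction / 2`. Planted
#' motif occurrences are placed uniformly at random without overlap;
#' degenerate IUPAC positions are resolved uniformly among their allowed
#' bases, independently per occurrence. Minus-strand plants insert the
#' reverse complement of the (resolved) motif into the plus-strand sequence.
#'
#' @param length Contig length(s) in bp. A named vector produces several
#'   contigs; unnamed contigs are called `contig_1`, `contig_2`, ...
#' @param gc_fraction GC content of the background sequence, in (0, 1).
#' @param plant_specs List of [plant_spec()] objects.
#' @param seed Integer seed; identical inputs and seed give byte-identical
#'   output.
#'
#' @return A list with elements `genome` (a [Biostrings::DNAStringSet]) and
#'   `planted`, a tibble of ground truth with columns `contig`, `start`
#'   (0-based plus-strand offset of the occurrence), `strand`, `motif_id`,
#'   `motif_len`, `focal_offset`, `focal_pos` (0-based genomic position of
#'   the focal base), `mod_multiplier` and a `context` list-column.
#' @export
#' @examples
#' sim <- generate_genome(5000, gc_fraction = 0.4,
#'                        plant_specs = list(plant_spec("GATC", 1, 5, 8.57)),
#'                        seed = 1)
#' sim$planted
generate_genome <- function(length, gc_fraction = 0.5, plant_specs = list(),
                            seed = 1L) {
  stopifnot(is.numeric(length), all(length >= 1),
            gc_fraction > 0, gc_fraction < 1)
  if (inherits(plant_specs, "plant_spec")) plant_specs <- list(plant_specs)
  footprint <- sum(vapply(plant_specs, function(s) nchar(s$motif) * s$count, 0))
  if (footprint >= sum(length)) {
    stop("total planted footprint (", footprint,
         ") must be smaller than the genome length", call. = FALSE)
  }
  withr::local_seed(seed)

  contig_names <- names(length)
  if (is.null(contig_names)) {
    contig_names <- paste0("contig_", seq_along(length))
  }
  probs <- c((1 - gc_fraction) / 2, gc_fraction / 2,
             gc_fraction / 2, (1 - gc_fraction) / 2)
  seqs <- lapply(length, function(L) {
    sample(.BASES, L, replace = TRUE, prob = probs)
  })
  names(seqs) <- contig_names

  occupied <- lapply(length, function(L) logical(L))
  names(occupied) <- contig_names
  planted <- list()

  for (spec in plant_specs) {
    len <- nchar(spec$motif)
    for (i in seq_len(spec$count)) {
      placed <- FALSE
      for (attempt in seq_len(1000L)) {
        ci <- if (base::length(seqs) == 1L) 1L else sample.int(base::length(seqs), 1L)
        L <- base::length(seqs[[ci]])
        if (L < len) next
        s0 <- sample.int(L - len + 1L, 1L) - 1L  # 0-based start
        idx <- (s0 + 1L):(s0 + len)
        if (any(occupied[[ci]][idx])) next
        resolved <- .resolve_iupac(spec$motif)
        inserted <- if (spec$strand == "+") resolved else .revcomp_chr(resolved)
        seqs[[ci]][idx] <- strsplit(inserted, "")[[1]]
        occupied[[ci]][idx] <- TRUE
        focal_pos <- if (spec$strand == "+") {
          s0 + spec$focal_offset
        } else {
          s0 + len - 1L - spec$focal_offset
        }
        planted[[base::length(planted) + 1L]] <- tibble(
          contig = contig_names[ci], start = s0, strand = spec$strand,
          motif_id = spec$motif, motif_len = len,
          focal_offset = spec$focal_offset, focal_pos = focal_pos,
          mod_multiplier = spec$mod_multiplier,
          context = list(spec$context)
        )
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place occurrence ", i, " of motif '", spec$motif,
             "': planting density infeasible", call. = FALSE)
      }
    }
  }

  genome <- Biostrings::DNAStringSet(
    vapply(seqs, paste0, character(1), collapse = "")
  )
  names(genome) <- contig_names
  planted_tbl <- if (base::length(planted)) {
    dplyr::bind_rows(planted)
  } else {
    tibble(contig = character(), start = integer(), strand = character(),
           motif_id = character(), motif_len = integer(),
           focal_offset = integer(), focal_pos = integer(),
           mod_multiplier = numeric(), context = list())
  }
  list(genome = genome, planted = planted_tbl)
}

# expand planted ground truth into a per-(contig,pos,strand) multiplier table
.planted_multipliers <- function(planted, mode) {
  if (is.null(planted) || nrow(planted) == 0) {
    return(tibble(contig = character(), pos = integer(),
                  strand = character(), mult = numeric()))
  }
  rows <- purrr::pmap(planted, function(contig, start, strand, motif_len,
                                        focal_pos, mod_multiplier, context, ...) {
    out <- tibble(contig = character(), pos = integer(),
                  strand = character(), mult = numeric())
    if (!is.null(context)) {
      rel <- as.integer(names(context))
      pos <- if (strand == "+") start + rel else start + motif_len - 1L - rel
      out <- tibble(contig = contig, pos = pos, strand = strand,
                    mult = unname(context))
    }
    if (mode == "native" && mod_multiplier != 1) {
      out <- dplyr::bind_rows(out, tibble(
        contig = contig, pos = as.integer(focal_pos), strand = strand,
        mult = mod_multiplier
      ))
    }
    out
  })
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$contig, .data$pos, .data$strand) |>
    dplyr::summarise(mult = prod(.data$mult), .groups = "drop")
}

#' Simulate read-level IPD observations
#'
#' Per site and strand, the number of observations is Poisson with mean
#' `coverage_per_strand`. See [kinetics_config()] for the generative law.
#' Modification multipliers of planted sites are applied only when
#' `mode = "native"`; sequence-context multipliers are applied in both modes
#' (they are properties of the sequence, not of the modification state).
#' The base read on the minus strand is the complement of the plus-strand
#' reference base at the same coordinate.
#'
#' @param genome A [Biostrings::DNAStringSet] (or the list returned by
#'   [generate_genome()]).
#' @param planted Ground-truth tibble from [generate_genome()], or `NULL`.
#' @param config A [kinetics_config()].
#' @param mode `"native"` (modifications present) or `"wga"`
#'   (whole-genome-amplified negative control; modification multipliers not
#'   applied).
#' @param seed Integer seed.
#'
#' @return A tibble of observations with columns `read_id`, `contig`, `pos`
#'   (0-based), `strand`, `ref_base` (base read on that strand), `ipd`,
#'   `neighbors_match`.
#' @export
simulate_reads <- function(genome, planted = NULL,
                           config = kinetics_config(),
                           mode = c("native", "wga"), seed = 1L) {
  mode <- match.arg(mode)
  genome <- as_genome(genome)
  stopifnot(inherits(config, "kinetics_config"))
  withr::local_seed(seed)

  mult_tbl <- .planted_multipliers(planted, mode)
  chunks <- list()
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    plus <- strsplit(as.character(genome[[ci]]), "")[[1]]
    for (strand in c("+", "-")) {
      bases <- if (strand == "+") plus else .complement_chr(plus)
      mu <- unname(config$base_mean_ipd[bases])
      ok <- !is.na(mu)  # skip reference N positions
      mult <- rep(1, base::length(bases))
      if (nrow(mult_tbl)) {
        mt <- mult_tbl[mult_tbl$contig == contig & mult_tbl$strand == strand, ]
        keep <- mt$pos >= 0 & mt$pos < base::length(bases)
        mult[mt$pos[keep] + 1L] <- mt$mult[keep]
      }
      counts <- rpois(base::length(bases), config$coverage_per_strand)
      counts[!ok] <- 0L
      idx <- rep.int(seq_along(bases), counts)
      n <- base::length(idx)
      if (n == 0) next
      ipd <- mu[idx] * mult[idx]
      if (config$log_sigma > 0) {
        s <- config$log_sigma
        ipd <- ipd * exp(s * rnorm(n) - s^2 / 2)
      }
      if (config$outlier_prob > 0) {
        out <- runif(n) < config$outlier_prob
        ipd[out] <- ipd[out] * config$outlier_scale
      }
      nb <- runif(n) >= config$neighbor_mismatch_prob
      chunks[[base::length(chunks) + 1L]] <- tibble(
        contig = contig, pos = idx - 1L, strand = strand,
        ref_base = bases[idx], ipd = ipd, neighbors_match = nb
      )
    }
  }
  obs <- dplyr::bind_rows(chunks)
  if (nrow(obs) == 0) {
    return(tibble(read_id = character(), contig = character(),
                  pos = integer(), strand = character(),
                  ref_base = character(), ipd = numeric(),
                  neighbors_match = logical()))
  }
  dplyr::mutate(obs, read_id = paste0("rd", dplyr::row_number()),
                .before = 1)
}

#' Coerce to a DNAStringSet genome
#'
#' @param x A `DNAStringSet`, a named character vector of sequences, or a
#'   list with a `genome` element (as returned by [generate_genome()]).
#' @return A [Biostrings::DNAStringSet] with unique, non-empty contig names.
#' @export
as_genome <- function(x) {
  if (is.list(x) && !is.null(x$genome)) x <- x$genome
  if (is.character(x)) {
    nm <- names(x)
    x <- Biostrings::DNAStringSet(toupper(x))
    names(x) <- if (is.null(nm)) paste0("contig_", seq_along(x)) else nm
  }
  stopifnot(methods::is(x, "DNAStringSet"), !is.null(names(x)),
            !anyDuplicated(names(x)), all(Biostrings::width(x) > 0))
  x
}

#' Read a genome from a FASTA file
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome to FASTA (60-column wrap)
#' @param genome See [as_genome()].
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path, width = 60L)
  invisible(path)
}

#' Write a simulated dataset to disk
#'
#' Writes the per-read IPD TSV (columns `read_id`, `contig`, `pos` 1-based,
#' `strand`, `ref_base`, `ipd`, `neighbors_match` 0/1) and, when ground
#' truth is supplied, a BED file of planted focal sites (0-based half-open;
#' `name = motif_id:focal_offset`, `score = round(100 * mod_multiplier)`).
#'
#' @param observations Tibble from [simulate_reads()].
#' @param dir Output directory (created if missing).
#' @param planted Optional ground-truth tibble from [generate_genome()].
#' @param genome Optional genome, written as `genome.fa`.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(observations, dir, planted = NULL, genome = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(reads = file.path(dir, "reads.tsv"))
  out <- dplyr::mutate(observations,
                       pos = .data$pos + 1L,
                       neighbors_match = as.integer(.data$neighbors_match))
  readr::write_tsv(out, paths[["reads"]])
  if (!is.null(planted) && nrow(planted) > 0) {
    paths[["planted"]] <- file.path(dir, "planted.bed")
    bed <- sprintf("%s\t%d\t%d\t%s:%d\t%d\t%s",
                   planted$contig, planted$focal_pos, planted$focal_pos + 1L,
                   planted$motif_id, planted$focal_offset,
                   round(100 * planted$mod_multiplier), planted$strand)
    writeLines(bed, paths[["planted"]])
  }
  if (!is.null(genome)) {
    paths[["genome"]] <- file.path(dir, "genome.fa")
    write_genome_fasta(genome, paths[["genome"]])
  }
  invisible(paths)
}

#' Read a per-read IPD TSV written by [write_dataset()]
#' @param path Path to `reads.tsv` or the dataset directory.
#' @return Observation tibble (0-based `pos`, logical `neighbors_match`).
#' @export
read_dataset <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "reads.tsv")
  readr::read_tsv(
    path,
    col_types = readr::cols(
      read_id = readr::col_character(), contig = readr::col_character(),
      pos = readr::col_integer(), strand = readr::col_character(),
      ref_base = readr::col_character(), ipd = readr::col_double(),
      neighbors_match = readr::col_integer()
    )
  ) |>
    dplyr::mutate(pos = .data$pos - 1L,
                  neighbors_match = .data$neighbors_match == 1L)
}

#' Occurrence tibble of planted motif sites
#' @param planted Ground-truth tibble from [generate_genome()] (or the full
#'   returned list).
#' @return Tibble with columns `contig`, `start`, `strand` — the same shape
#'   as [scan_motif()] output, restricted to planted occurrences.
#' @export
planted_occurrences <- function(planted) {
  if (is.list(planted) && !is.data.frame(planted) && !is.null(planted$planted)) {
    planted <- planted$planted
  }
  tibble(contig = planted$contig, start = as.integer(planted$start),
         strand = planted$strand)
}

#' Loci tibble of planted focal sites
#' @param planted Ground-truth tibble from [generate_genome()].
#' @return Tibble with columns `contig`, `pos`, `strand`, one row per
#'   planted focal base — suitable for [compare_native_wga()].
#' @export
planted_loci <- function(planted) {
  if (is.list(planted) && !is.data.frame(planted) && !is.null(planted$planted)) {
    planted <- planted$planted
  }
  tibble(contig = planted$contig, pos = as.integer(planted$focal_pos),
         strand = planted$strand)
}
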