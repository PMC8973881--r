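#' Build a pipeline configuration
#'
#' A single declarative description of a full analysis run: simulate (or
#' load) paired native/WGA kinetics, aggregate per-site summaries, profile
#' and compare motifs, detect extreme loci, optionally test feature
#' enrichment and replicate concordance. Serialisable to/from JSON.
#'
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param genome_length,gc_fraction Synthetic genome size and GC content.
#' @param plants List of plant descriptions, each a list with `motif`,
#'   `focal` (1-based), `count`, `mod_multiplier` and optional `context`
#'   (named multipliers, names = 0-based relative offsets).
#' @param motifs List of motifs to analyse, each a list with `motif` and
#'   `focal` (1-based).
#' @param kinetics Named list overriding [kinetics_config()] defaults.
#' @param min_valid,pct,flank,window,alpha,fold_call Thresholds: coverage
#'   filter, extreme percentile, profile flank, export window width,
#'   significance level, and the minimum native/WGA fold for calling a
#'   motif modified.
#' @param annotations Optional BED/GFF3 path of region annotations for the
#'   enrichment stage.
#' @param replicate_concordance Simulate a second WGA replicate and run
#'   the concordance stage. Default `TRUE`.
#' @param write_reads Write the (large) per-read TSVs. Default `FALSE`.
#' @param inputs Optional named list of paths (`genome`, `reads_native`,
#'   `reads_wga`) to analyse existing data instead of simulating.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            genome_length = 30000,
                            gc_fraction = 0.5,
                            plants = list(),
                            motifs = list(),
                            kinetics = list(),
                            min_valid = 25, pct = 1.0, flank = 10,
                            window = 41, alpha = 0.01, fold_call = 2,
                            annotations = NULL,
                            replicate_concordance = TRUE,
                            write_reads = FALSE,
                            inputs = NULL) {
  cfg <- list(seed = as.integer(seed), genome_length = genome_length,
              gc_fraction = gc_fraction, plants = plants, motifs = motifs,
              kinetics = kinetics, min_valid = min_valid, pct = pct,
              flank = flank, window = window, alpha = alpha,
              fold_call = fold_call, annotations = annotations,
              replicate_concordance = replicate_concordance,
              write_reads = write_reads, inputs = inputs,
              config_version = 1L)
  stopifnot(cfg$min_valid >= 0, cfg$pct > 0, cfg$pct < 50, cfg$flank >= 0,
            cfg$window %% 2 == 1, cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  raw$config_version <- NULL
  # scalars arrive as length-1 lists; unwrap leaves
  unwrap <- function(x) if (is.list(x) && length(x) == 1 && !is.list(x[[1]]) &&
                              is.null(names(x))) x[[1]] else x
  for (nm in setdiff(names(raw), c("plants", "motifs", "kinetics", "inputs"))) {
    raw[[nm]] <- unwrap(raw[[nm]])
    if (is.list(raw[[nm]]) && length(raw[[nm]]) == 0) raw[[nm]] <- NULL
  }
  raw$kinetics <- lapply(raw$kinetics, unlist)
  do.call(pipeline_config, raw)
}

.plants_from_config <- function(plants) {
  lapply(plants, function(p) {
    ctx <- if (!is.null(p$context)) unlist(p$context) else NULL
    plant_spec(p$motif, focal_offset = p$focal - 1L, count = p$count,
               mod_multiplier = p$mod_multiplier %||% 1,
               context = ctx, strand = p$strand %||% "+")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full IPD analysis pipeline
#'
#' Executes the stages simulate (or load) -> aggregate -> motif
#' profile/compare -> extreme loci -> enrichment -> concordance in
#' dependency order, writing deterministically named outputs plus a
#' machine-readable `summary.json` and a `run.log`. Re-running with an
#' identical configuration reproduces identical outputs. A stage failure
#' aborts with the stage name; partial outputs are kept next to a
#' `FAILED` marker file.
#'
#' @param config A [pipeline_config()] or path to its JSON form.
#' @param out_dir Output directory (created).
#' @return Invisibly, the summary list (also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  say <- function(...) {
    line <- paste0(...)
    message("[ipdkin] ", line)
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
  }
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e) {
      writeLines(paste0("failed at stage: ", name, "\n", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  summary <- list(seed = config$seed, stages = list())
  kin <- do.call(kinetics_config, as.list(config$kinetics))

  # --- simulate / load ------------------------------------------------
  sim <- stage("simulate", {
    if (!is.null(config$inputs)) {
      genome <- read_genome_fasta(config$inputs$genome)
      list(genome = genome, planted = NULL,
           native = read_dataset(config$inputs$reads_native),
           wga = read_dataset(config$inputs$reads_wga), wga2 = NULL)
    } else {
      g <- generate_genome(config$genome_length, config$gc_fraction,
                           .plants_from_config(config$plants),
                           seed = config$seed + 1L)
      native <- simulate_reads(g, g$planted, kin, "native",
                               seed = config$seed + 2L)
      wga <- simulate_reads(g, g$planted, kin, "wga",
                            seed = config$seed + 3L)
      wga2 <- if (isTRUE(config$replicate_concordance)) {
        simulate_reads(g, g$planted, kin, "wga", seed = config$seed + 4L)
      }
      write_genome_fasta(g$genome, file.path(out_dir, "genome.fa"))
      if (!is.null(g$planted) && nrow(g$planted)) {
        bed <- sprintf("%s\t%d\t%d\t%s:%d\t%d\t%s",
                       g$planted$contig, g$planted$focal_pos,
                       g$planted$focal_pos + 1L, g$planted$motif_id,
                       g$planted$focal_offset,
                       round(100 * g$planted$mod_multiplier),
                       g$planted$strand)
        writeLines(bed, file.path(out_dir, "planted.bed"))
      }
      if (isTRUE(config$write_reads)) {
        write_dataset(native, file.path(out_dir, "native"))
        write_dataset(wga, file.path(out_dir, "wga"))
      }
      list(genome = g$genome, planted = g$planted, native = native,
           wga = wga, wga2 = wga2)
    }
  })
  summary$stages$simulate <- list(
    n_contigs = length(sim$genome),
    genome_bp = sum(Biostrings::width(sim$genome)),
    n_planted = if (is.null(sim$planted)) 0L else nrow(sim$planted),
    n_obs_native = nrow(sim$native), n_obs_wga = nrow(sim$wga)
  )

  # --- aggregate ------------------------------------------------------
  agg <- stage("aggregate", {
    nat <- aggregate_sites(sim$native, min_valid = config$min_valid)
    wga <- aggregate_sites(sim$wga, min_valid = config$min_valid)
    wga2 <- if (!is.null(sim$wga2)) {
      aggregate_sites(sim$wga2, min_valid = config$min_valid)
    }
    write_sites_csv(nat, file.path(out_dir, "sites_native.csv"))
    write_sites_csv(wga, file.path(out_dir, "sites_wga.csv"))
    if (!is.null(wga2)) {
      write_sites_csv(wga2, file.path(out_dir, "sites_wga2.csv"))
    }
    list(native = nat, wga = wga, wga2 = wga2)
  })
  base_means <- genome_base_means(agg$wga)
  summary$stages$aggregate <- list(
    n_sites_native = nrow(agg$native), n_sites_wga = nrow(agg$wga),
    base_means_wga = setNames(as.list(round(base_means$mean_ipd, 6)),
                              base_means$ref_base)
  )

  # --- motifs ---------------------------------------------------------
  if (length(config$motifs) > 0) {
    motif_tbl <- stage("motifs", {
      n_tests <- sum(vapply(config$motifs, function(m) {
        nchar(m$motif) + 2L * config$flank
      }, 0))
      rows <- lapply(config$motifs, function(m) {
        occ <- scan_motif(sim$genome, m$motif)
        prof <- motif_profile(agg$wga, occ, m$motif, flank = config$flank)
        roi <- ratio_of_increase(prof, agg$wga, m$focal - 1L)
        roi <- roi[roi$focal_base != "pooled", ][1, ]
        cmp <- compare_native_wga(agg$native, agg$wga,
                                  focal_loci(occ, m$motif, m$focal - 1L))
        ext <- test_motif_extremeness(prof, agg$wga, n_tests = n_tests,
                                      alpha = config$alpha)
        tibble(
          motif = m$motif, focal = m$focal, n_occurrences = nrow(occ),
          n_loci = cmp$n_loci,
          mean_ipd_motif = roi$mean_ipd_motif,
          mean_ipd_genome = roi$mean_ipd_genome,
          ratio_of_increase = roi$ratio_of_increase,
          ranksum_p = roi$ranksum_p,
          native_wga_fold = cmp$native_wga_fold,
          native_wga_p = cmp$native_wga_p,
          min_extreme_p_adj = suppressWarnings(
            min(ext$p_adjusted, na.rm = TRUE)
          ),
          called_modified = cmp$native_wga_fold >= config$fold_call &
            cmp$native_wga_p < config$alpha
        )
      })
      tbl <- dplyr::bind_rows(rows)
      readr::write_tsv(tbl, file.path(out_dir, "motif_comparisons.tsv"))
      tbl
    })
    summary$stages$motifs <- list(
      n_motifs = nrow(motif_tbl),
      called_modified = motif_tbl$motif[motif_tbl$called_modified],
      table = lapply(seq_len(nrow(motif_tbl)), function(i) {
        as.list(dplyr::mutate(
          motif_tbl[i, ],
          dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 8))
        ))
      })
    )
  }

  # --- extremes -------------------------------------------------------
  ext <- stage("extremes", {
    e <- detect_extreme_loci(agg$wga, pct = config$pct)
    write_loci_bed(e, file.path(out_dir, "extreme_loci.bed"))
    export_windows(e, sim$genome, width = config$window,
                   path = file.path(out_dir, "extreme_windows.fa"))
    e
  })
  summary$stages$extremes <- list(
    n_high = sum(ext$loci$class == "high"),
    n_low = sum(ext$loci$class == "low"),
    hi_threshold = signif(ext$hi_threshold, 8),
    lo_threshold = signif(ext$lo_threshold, 8)
  )

  # --- enrichment -----------------------------------------------------
  if (!is.null(config$annotations)) {
    enr <- stage("enrich", {
      regions <- if (grepl("\\.(gff3?|gff)$", config$annotations,
                           ignore.case = TRUE)) {
        read_regions_gff3(config$annotations)
      } else {
        read_regions_bed(config$annotations)
      }
      res <- region_enrichment(ext, regions, agg$wga)
      readr::write_tsv(res, file.path(out_dir, "enrichment.tsv"))
      res
    })
    summary$stages$enrich <- list(
      n_labels = length(unique(enr$label)),
      n_significant_q = sum(enr$q_adjusted < 0.001, na.rm = TRUE)
    )
  }

  # --- concordance ----------------------------------------------------
  if (!is.null(agg$wga2)) {
    conc <- stage("concord", {
      # re-aggregate without the >=25 filter so the low-coverage end of the
      # grid is populated
      grid <- c(5, 10, 15, 20, 25)
      wga_lo <- aggregate_sites(sim$wga, min_valid = min(grid))
      wga2_lo <- aggregate_sites(sim$wga2, min_valid = min(grid))
      rr <- replicate_ratio_by_coverage(wga_lo, wga2_lo,
                                        coverage_grid = grid)
      readr::write_tsv(rr, file.path(out_dir, "replicate_ratio.tsv"))
      rr
    })
    summary$stages$concord <- list(
      sd_by_coverage = setNames(as.list(signif(conc$sd, 8)),
                                paste0("cov", conc$min_coverage))
    )
  }

  say("writing summary.json")
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  say("done")
  invisible(summary)
}
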