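process_sector <- function(probe_table, map, thresholds) {
  calls <- call_genotypes(map, normalize_ratios(probe_table), thresholds)
  resolve_ambiguous(calls)
}

#' Run the full simulate-genotype-classify-enrich pipeline
#'
#' Simulates a cohort of red/white sectored colonies and sub-cultured
#' isolates, renders noisy two-channel probe intensities for every sample,
#' calls genotypes, detects the selected crossover and its conversion tract
#' in each colony, classifies unselected events genome-wide, summarizes
#' SCB/DSCB fractions and tract lengths, and (when an element table is
#' supplied) computes the breakpoint association-window enrichment table.
#' Every stage is a pure function of (inputs, seed): reruns with the same
#' arguments reproduce identical outputs.
#'
#' @param n_colonies number of sectored colonies.
#' @param n_isolates number of sub-cultured isolates.
#' @param events_per_isolate unselected events per isolate (default 10).
#' @param config a \code{sim_config}.
#' @param thresholds a \code{call_thresholds}.
#' @param elements optional element table (class_name, chrom, start, end) or
#'   path to a BED file; enrichment is skipped with a log line when absent.
#' @param seed master seed; per-sample substreams are derived from it.
#' @param outdir optional output directory for TSV reports.
#' @param q FDR level for the enrichment correction.
#' @param verbose emit one log line per stage (default TRUE).
#' @return list with map, selected_events, unselected_events, dscb_fraction,
#'   tract_stats, type_counts, enrichment, n_genomes, seed.
#' @export
run_pipeline <- function(n_colonies = 5, n_isolates = 5,
                         events_per_isolate = 10,
                         config = sim_config(), thresholds = call_thresholds(),
                         elements = NULL, seed = 1, outdir = NULL, q = 0.05,
                         verbose = TRUE) {
  log_line <- function(...) if (verbose) message("[lohmapper] ", ...)
  if (is.character(elements)) elements <- read_elements_bed(elements)
  map <- simulate_snp_map(config, seed = seed)
  log_line("marker map: ", nrow(map), " markers on ",
           length(unique(map$chrom)), " chromosomes (seed ", seed, ")")

  selected <- list()
  unselected <- list()
  for (i in seq_len(n_colonies)) {
    s <- (seed + i * 1009L) %% 2147483647L
    cid <- sprintf("colony%03d", i)
    sim <- simulate_sectored_colony(config, seed = s, map = map, colony_id = cid)
    red <- process_sector(render_probe_intensities(sim$red, map, config, s),
                          map, thresholds)
    white <- process_sector(render_probe_intensities(sim$white, map, config, s + 1L),
                            map, thresholds)
    det <- detect_selected_crossover(red, white, map,
                                     sel_locus = config$sel_locus,
                                     centromere = config$centromere_V,
                                     min_markers = config$min_tract_markers,
                                     chrom_length = config$chrom_lengths[["chrV"]])
    if (det$selected) {
      ev <- det$event
      ev$sample_id <- cid
      selected[[length(selected) + 1]] <- ev
    } else {
      log_line(cid, ": selection failure flag")
    }
    for (sec in list(red, white)) {
      ue <- classify_unselected_events(sec, map, config$chrom_lengths,
                                       sample_id = cid,
                                       min_markers = config$min_tract_markers)
      unselected[[length(unselected) + 1]] <- ue[ue$chrom != "chrV", , drop = FALSE]
    }
  }
  log_line(n_colonies, " colonies: ", length(selected), " selected crossovers")

  for (i in seq_len(n_isolates)) {
    s <- (seed + 500000L + i * 2003L) %% 2147483647L
    iid <- sprintf("isolate%03d", i)
    sim <- simulate_subcultured_isolate(config, seed = s,
                                        n_events = events_per_isolate,
                                        map = map, sample_id = iid)
    calls <- process_sector(render_probe_intensities(sim$track, map, config, s),
                            map, thresholds)
    unselected[[length(unselected) + 1]] <- classify_unselected_events(
      calls, map, config$chrom_lengths, sample_id = iid,
      min_markers = config$min_tract_markers)
  }
  log_line(n_isolates, " isolates processed")

  selected_events <- if (length(selected))
    do.call(rbind, c(selected, make.row.names = FALSE)) else empty_events()
  unselected_events <- if (length(unselected))
    do.call(rbind, c(unselected, make.row.names = FALSE)) else empty_events()
  if (nrow(unselected_events) > 0)
    unselected_events$event_id <- sprintf("ev%04d", seq_len(nrow(unselected_events)))
  if (nrow(selected_events) > 0)
    selected_events$event_id <- paste0(selected_events$sample_id, "_selCO")

  classified <- selected_events$origin %in% c("SCB", "DSCB")
  dscb_fraction <- if (any(classified))
    mean(selected_events$origin[classified] == "DSCB") else NA_real_

  tract_stats <- lapply(c(DSCB = "DSCB", SCB = "SCB"), function(or) {
    len <- selected_events$length[selected_events$origin == or &
                                    !is.na(selected_events$length)]
    if (length(len) == 0) return(NULL)
    c(n = length(len), median_with_ci(len))
  })
  type_counts <- table(unselected_events$type)
  log_line("events: ", nrow(selected_events), " selected, ",
           nrow(unselected_events), " unselected")

  n_genomes <- n_colonies + n_isolates
  enrichment <- NULL
  if (is.null(elements)) {
    log_line("no element annotation supplied; enrichment stage skipped")
  } else {
    windows <- build_association_windows(unselected_events, config$chrom_lengths)
    enrichment <- enrichment_table(windows, elements, n_genomes,
                                   analyzed_bp = config$analyzed_bp, q = q)
    log_line("enrichment: ", nrow(enrichment), " classes, ",
             sum(enrichment$significant), " significant at q=", q)
  }

  result <- list(map = map, selected_events = selected_events,
                 unselected_events = unselected_events,
                 dscb_fraction = dscb_fraction, tract_stats = tract_stats,
                 type_counts = type_counts, enrichment = enrichment,
                 n_genomes = n_genomes, seed = seed)
  class(result) <- "loh_pipeline_result"

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    hdr <- paste0("lohmapper seed=", seed)
    write_events(selected_events, file.path(outdir, "selected_events.tsv"), hdr)
    write_events(unselected_events, file.path(outdir, "unselected_events.tsv"), hdr)
    if (!is.null(enrichment))
      write.table(enrichment, file.path(outdir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("reports written to ", outdir)
  }
  result
}

#' @export
print.loh_pipeline_result <- function(x, ...) {
  cat("LOH mapping pipeline result (seed ", x$seed, ")\n", sep = "")
  cat("  genomes analyzed: ", x$n_genomes, "\n", sep = "")
  cat("  selected crossovers: ", nrow(x$selected_events), "\n", sep = "")
  if (!is.na(x$dscb_fraction))
    cat("  DSCB fraction among classified tracts: ",
        round(x$dscb_fraction, 3), "\n", sep = "")
  for (or in names(x$tract_stats)) {
    ts <- x$tract_stats[[or]]
    if (!is.null(ts))
      cat("  ", or, " tract median: ", round(ts$median / 1000, 1), " kb (",
          round(ts$ci_lo / 1000, 1), "-", round(ts$ci_hi / 1000, 1),
          " kb, 95% CI, n=", ts$n, ")\n", sep = "")
  }
  if (nrow(x$unselected_events) > 0) {
    cat("  unselected events:\n")
    for (ty in names(x$type_counts))
      cat("    ", ty, ": ", x$type_counts[[ty]], "\n", sep = "")
  }
  if (!is.null(x$enrichment))
    cat("  enrichment: ", sum(x$enrichment$significant), " of ",
        nrow(x$enrichment), " classes significant\n", sep = "")
  invisible(x)
}
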