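#' Build breakpoint association windows
#'
#' The association window of an event is the interval presumed to contain the
#' initiating recombinogenic lesion. For terminal events (terminal LOH,
#' terminal duplication/deletion) it extends 10 kb to each side of the
#' homozygous SNP nearest the breakpoint, clipped to the chromosome; for
#' interstitial conversions it spans all sequence between the heterozygous
#' SNPs flanking the LOH region. Trisomies and events without resolvable
#' boundary markers are excluded with a warning. Overlapping windows within
#' one genome are merged before any bp summation so sequence is never counted
#' twice.
#'
#' @param events classified events data.frame.
#' @param chrom_lengths named chromosome lengths used for clipping.
#' @param flank half-width of terminal-event windows in bp (default 10000).
#' @return data.frame with sample_id, chrom, start, end (1-based inclusive,
#'   merged per genome).
#' @export
build_association_windows <- function(events, chrom_lengths, flank = 10000) {
  terminal <- c("BIR_OR_CO_TERMINAL", "TERMINAL_DUP", "TERMINAL_DEL", "CO")
  rows <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$type == "TRISOMY") next
    if (ev$type %in% terminal) {
      if (is.na(ev$hom_boundary)) {
        warning("event ", ev$event_id, " has no resolvable boundary; excluded")
        next
      }
      len <- chrom_lengths[[ev$chrom]]
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = ev$sample_id, chrom = ev$chrom,
        start = max(1, ev$hom_boundary - flank),
        end = min(len, ev$hom_boundary + flank), stringsAsFactors = FALSE)
    } else if (ev$type == "GC_INTERSTITIAL") {
      if (is.na(ev$t1_proximal) || is.na(ev$t2_distal)) {
        warning("event ", ev$event_id, " has no resolvable boundary; excluded")
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = ev$sample_id, chrom = ev$chrom,
        start = ev$t1_proximal, end = ev$t2_distal, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      stringsAsFactors = FALSE))
  win <- do.call(rbind, c(rows, make.row.names = FALSE))
  merge_windows(win)
}

#' Merge overlapping windows within each genome
#' @param windows data.frame with sample_id, chrom, start, end.
#' @return merged windows, same columns; idempotent.
#' @export
merge_windows <- function(windows) {
  if (nrow(windows) == 0) return(windows)
  out <- lapply(split(windows, windows$sample_id), function(w) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      w$chrom, IRanges::IRanges(w$start, w$end)))
    data.frame(sample_id = w$sample_id[1],
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Count genomic elements inside and outside association windows
#'
#' An element is "inside" when it overlaps a window of that genome by at
#' least one bp (switchable to midpoint containment). Elements are counted
#' per genome and summed over the \code{n_genomes} analyzed; genomes without
#' any window contribute zero inside-counts. The expected inside-count is the
#' total element count times the fraction of analyzed sequence covered by
#' windows.
#'
#' @param windows merged windows (sample_id, chrom, start, end).
#' @param elements element table (class_name, chrom, start, end), giving the
#'   per-genome complement of each class.
#' @param n_genomes number of genomes analyzed.
#' @param analyzed_bp analyzed genome size per genome (default 11.6e6).
#' @param mode "overlap" (default) or "midpoint".
#' @return data.frame per class: n_per_genome, total, window_bp, expected_in,
#'   expected_out, observed_in, observed_out.
#' @export
count_elements <- function(windows, elements, n_genomes,
                           analyzed_bp = 11.6e6, mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  windows <- merge_windows(windows)
  window_bp <- sum(windows$end - windows$start + 1)
  universe_bp <- n_genomes * analyzed_bp
  if (window_bp > universe_bp)
    stop("summed window bp exceeds the analyzed universe")
  el <- elements
  if (mode == "midpoint") {
    mid <- floor((el$start + el$end) / 2)
    el_gr <- GenomicRanges::GRanges(el$chrom, IRanges::IRanges(mid, mid))
  } else {
    el_gr <- GenomicRanges::GRanges(el$chrom, IRanges::IRanges(el$start, el$end))
  }
  classes <- sort(unique(el$class_name))
  obs_in <- setNames(numeric(length(classes)), classes)
  for (sid in unique(windows$sample_id)) {
    w <- windows[windows$sample_id == sid, ]
    w_gr <- GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start, w$end))
    # seqlevel mismatch between element and window ranges is expected
    hit <- suppressWarnings(IRanges::overlapsAny(el_gr, w_gr))
    if (any(hit)) {
      tab <- table(el$class_name[hit])
      obs_in[names(tab)] <- obs_in[names(tab)] + as.numeric(tab)
    }
  }
  n_per <- as.numeric(table(el$class_name)[classes])
  total <- n_per * n_genomes
  exp_in <- total * window_bp / universe_bp
  data.frame(class_name = classes, n_per_genome = n_per, total = total,
             window_bp = window_bp,
             expected_in = exp_in, expected_out = total - exp_in,
             observed_in = as.numeric(obs_in),
             observed_out = total - as.numeric(obs_in),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Element-class enrichment table
#'
#' For every element class, compares the observed inside/outside counts with
#' their expectations by a 1-df goodness-of-fit chi-square (continuity
#' correction on by default) and applies the Hochberg-Benjamini step-up FDR
#' correction across classes. Rows whose expected inside-count is below 1 are
#' flagged; their p-values are still reported.
#'
#' @param windows merged association windows.
#' @param elements element table (class_name, chrom, start, end).
#' @param n_genomes number of genomes analyzed.
#' @param analyzed_bp analyzed genome size per genome.
#' @param q FDR level for the correction (default 0.05).
#' @param correction continuity correction flag for the chi-square.
#' @param mode element-inside rule, "overlap" or "midpoint".
#' @return data.frame: one row per class with counts, chisq, p, significant,
#'   low_expectation.
#' @export
enrichment_table <- function(windows, elements, n_genomes,
                             analyzed_bp = 11.6e6, q = 0.05,
                             correction = TRUE, mode = "overlap") {
  counts <- count_elements(windows, elements, n_genomes, analyzed_bp, mode)
  if (nrow(counts) == 0) stop("no element classes")
  res <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    if (r$expected_in <= 0 || r$expected_out <= 0)
      return(c(NA_real_, 1))
    gof <- chisq_gof_1df(r$observed_in, r$observed_out,
                         r$expected_in, r$expected_out, correction)
    c(gof$statistic, gof$p.value)
  })
  res <- do.call(rbind, res)
  counts$chisq <- res[, 1]
  counts$p <- res[, 2]
  counts$significant <- hochberg_benjamini(counts$p, q)
  counts$low_expectation <- counts$expected_in < 1
  counts
}
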