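#' @importFrom utils read.delim write.table
NULL

SNP_MAP_COLS <- c("chrom", "coord", "allele_a_id", "allele_b_id",
                  "probe_aw", "probe_ac", "probe_bw", "probe_bc")
PROBE_COLS <- c("probe_id", "exp_median", "ctrl_median")

validate_snp_map <- function(map) {
  missing <- setdiff(SNP_MAP_COLS, names(map))
  if (length(missing) > 0)
    stop("SNP map is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(map) == 0) return(map)
  if (any(map$coord < 1)) stop("marker coordinates must be >= 1")
  dup <- duplicated(map[, c("chrom", "coord")])
  if (any(dup))
    stop("duplicated (chrom, coord) in SNP map at line ", which(dup)[1] + 1L)
  # stable chromosome blocks, strictly increasing coordinates within each
  for (ch in unique(map$chrom)) {
    co <- map$coord[map$chrom == ch]
    bad <- which(diff(co) <= 0)
    if (length(bad) > 0) {
      line <- which(map$chrom == ch)[bad[1] + 1L] + 1L
      stop("non-monotone coordinates on ", ch, " at line ", line)
    }
  }
  probes <- unlist(map[, c("probe_aw", "probe_ac", "probe_bw", "probe_bc")],
                   use.names = FALSE)
  if (anyDuplicated(probes)) stop("probe identifiers are not distinct")
  class(map) <- c("snp_map", "data.frame")
  map
}

#' Read a SNP marker map
#'
#' Tab-separated file with header columns \code{chrom}, \code{coord} (1-based
#' bp), \code{allele_a_id}, \code{allele_b_id} and the four allele-specific
#' probe identifiers \code{probe_aw}, \code{probe_ac}, \code{probe_bw},
#' \code{probe_bc} (Watson/Crick oligos for each parental allele). Markers
#' must be unique per (chrom, coord) and strictly increasing within each
#' chromosome.
#'
#' @param path file path.
#' @return data.frame of class \code{snp_map}.
#' @export
read_snp_map <- function(path) {
  map <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "#")
  validate_snp_map(map)
}

#' Write a SNP marker map
#' @param map a \code{snp_map} data.frame.
#' @param path output path.
#' @export
write_snp_map <- function(map, path) {
  write.table(map[, SNP_MAP_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a two-channel probe intensity table
#'
#' Tab-separated with header columns \code{probe_id}, \code{exp_median}
#' (experimental channel) and \code{ctrl_median} (heterozygous control
#' channel), emulating a scanner text export reduced to per-probe medians.
#' Intensities must be positive. If a marker map is supplied, probes absent
#' from it are retained and flagged (\code{in_map = FALSE}) so that totals
#' remain auditable.
#'
#' @param path file path.
#' @param snp_map optional marker map used to flag unknown probes.
#' @return data.frame with columns probe_id, exp_median, ctrl_median, in_map.
#' @export
read_probe_table <- function(path, snp_map = NULL) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "#")
  missing <- setdiff(PROBE_COLS, names(tab))
  if (length(missing) > 0)
    stop("probe table is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(tab$probe_id))
    stop("repeated probe_id: ", tab$probe_id[duplicated(tab$probe_id)][1])
  if (any(tab$exp_median <= 0) || any(tab$ctrl_median <= 0))
    stop("probe intensities must be positive")
  tab$in_map <- if (is.null(snp_map)) NA else
    tab$probe_id %in% unlist(snp_map[, c("probe_aw", "probe_ac",
                                         "probe_bw", "probe_bc")])
  tab
}

#' Write a probe intensity table
#' @param probes data.frame with probe_id, exp_median, ctrl_median.
#' @param path output path.
#' @export
write_probe_table <- function(probes, path) {
  write.table(probes[, PROBE_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read genomic element annotations from BED
#'
#' BED input is 0-based half-open; elements are converted to the package's
#' 1-based inclusive convention (start + 1, end unchanged), which preserves
#' interval length. The element class is taken from the BED name field.
#'
#' @param path BED4 file path.
#' @return data.frame with columns class_name, chrom, start, end (1-based
#'   inclusive).
#' @export
read_elements_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(class_name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t| +")
  if (any(lengths(fields) < 4)) stop("BED line with fewer than 4 fields")
  raw_start <- as.numeric(vapply(fields, `[`, "", 2))
  raw_end <- as.numeric(vapply(fields, `[`, "", 3))
  if (any(raw_end <= raw_start))
    stop("BED interval with end <= start at line ",
         which(raw_end <= raw_start)[1])
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(class_name = as.character(gr$name),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write genomic elements to BED4 (converting back to 0-based half-open)
#' @param elements data.frame with class_name, chrom, start, end (1-based
#'   inclusive).
#' @param path output path.
#' @export
write_elements_bed <- function(elements, path) {
  bed <- data.frame(elements$chrom, elements$start - 1L, elements$end,
                    elements$class_name)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

EVENT_COLS <- c("event_id", "sample_id", "type", "chrom", "gaining_haplotype",
                "t1_proximal", "t1_distal", "t2_proximal", "t2_distal",
                "hom_boundary", "tract_class", "origin",
                "min_len", "max_len", "length")

SEGMENT_COLS <- c("sample_id", "chrom", "start_coord", "end_coord",
                  "state", "n_markers")

#' Write classified LOH events to a tab-separated report
#'
#' One row per event. Each LOH transition carries both boundary coordinates:
#' the last marker of the preceding zygosity state (\code{*_proximal}) and
#' the first marker of the following state (\code{*_distal}). Terminal events
#' have a single transition; interstitial events have two. Tract columns are
#' NA for events without a measurable conversion tract.
#'
#' @param events events data.frame (see \code{EVENT_COLS} for the schema).
#' @param path output path.
#' @param header_comment optional comment line(s) written with a leading '#'.
#' @export
write_events <- function(events, path, header_comment = NULL) {
  for (col in EVENT_COLS) if (!col %in% names(events)) events[[col]] <- NA
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  write.table(events[, EVENT_COLS], con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an events report written by \code{write_events}
#' @param path file path.
#' @return events data.frame.
#' @export
read_events <- function(path) {
  read.delim(path, header = TRUE, stringsAsFactors = FALSE,
             comment.char = "#")
}

#' Write zygosity segments to a tab-separated report
#' @param segments segments data.frame (sample_id, chrom, start_coord,
#'   end_coord, state, n_markers).
#' @param path output path.
#' @param header_comment optional '#' comment line(s).
#' @export
write_segments <- function(segments, path, header_comment = NULL) {
  for (col in SEGMENT_COLS) if (!col %in% names(segments)) segments[[col]] <- NA
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  write.table(segments[, SEGMENT_COLS], con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a segments report written by \code{write_segments}
#' @param path file path.
#' @return segments data.frame.
#' @export
read_segments <- function(path) {
  read.delim(path, header = TRUE, stringsAsFactors = FALSE,
             comment.char = "#")
}
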