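#' Genotype-calling thresholds
#'
#' Decision boundaries for per-marker zygosity and copy-state calls, placed
#' midway between the expected state means of the normalized hybridization
#' ratios (heterozygous ~1, homozygous-matching ~1.5, homozygous-mismatching
#' ~0.2-0.3).
#'
#' @param het_lo,het_hi heterozygous band on the per-allele mean ratio.
#' @param hom_match_min minimum mean ratio of the matching allele for a
#'   homozygous call.
#' @param hom_mismatch_max maximum mean ratio of the mismatching allele.
#' @param del_max below this, an allele is treated as lost (copy-loss band).
#' @param dup_lo,dup_hi band for the gained allele of a copy-gain state.
#' @param dup_other_lo,dup_other_hi band for the other allele of a copy-gain.
#' @return list of class \code{call_thresholds}.
#' @export
call_thresholds <- function(het_lo = 0.7, het_hi = 1.3,
                            hom_match_min = 1.35, hom_mismatch_max = 0.5,
                            del_max = 0.5,
                            dup_lo = 1.15, dup_hi = 1.45,
                            dup_other_lo = 0.6, dup_other_hi = 0.95) {
  if (!(het_lo < het_hi && het_hi < hom_match_min))
    stop("thresholds must satisfy het_lo < het_hi < hom_match_min")
  th <- as.list(environment())
  class(th) <- "call_thresholds"
  th
}

#' Normalize probe hybridization ratios
#'
#' Computes the raw experimental/control ratio per probe and rescales all
#' ratios by a single global constant so the genome-wide median ratio is 1.
#' Because most of a typical genome remains heterozygous, this anchors the
#' heterozygous state at ratio ~1 and homozygous states at ~1.5 / ~0.25.
#'
#' @param probe_table data.frame with probe_id, exp_median, ctrl_median.
#' @return the table with added columns \code{raw_ratio} and \code{ratio}.
#' @export
normalize_ratios <- function(probe_table) {
  if (nrow(probe_table) == 0) stop("probe table is empty")
  if (any(probe_table$ctrl_median <= 0))
    stop("control channel must be positive")
  raw <- probe_table$exp_median / probe_table$ctrl_median
  med <- stats::median(raw)
  if (med <= 0) stop("degenerate probe table: nonpositive median ratio")
  probe_table$raw_ratio <- raw
  probe_table$ratio <- raw / med
  probe_table
}

ZYGOSITY_STATES <- c("HET", "HOM_A", "HOM_B", "AMBIGUOUS")

call_one <- function(mean_a, mean_b, th) {
  if (is.na(mean_a) || is.na(mean_b)) return("AMBIGUOUS")
  in_het <- function(x) x >= th$het_lo & x <= th$het_hi
  if (in_het(mean_a) && in_het(mean_b)) return("HET")
  if (mean_a >= th$hom_match_min && mean_b <= th$hom_mismatch_max) return("HOM_A")
  if (mean_b >= th$hom_match_min && mean_a <= th$hom_mismatch_max) return("HOM_B")
  "AMBIGUOUS"
}

copy_one <- function(mean_a, mean_b, th) {
  if (is.na(mean_a) || is.na(mean_b)) return("NORMAL")
  in_band <- function(x, lo, hi) x >= lo & x <= hi
  # one allele near the heterozygous level, the other collapsed: copy loss
  if (in_band(mean_a, th$het_lo, th$het_hi) && mean_b <= th$del_max) return("DEL")
  if (in_band(mean_b, th$het_lo, th$het_hi) && mean_a <= th$del_max) return("DEL")
  # one allele mildly elevated, the other mildly depressed: copy gain
  if (in_band(mean_a, th$dup_lo, th$dup_hi) &&
      in_band(mean_b, th$dup_other_lo, th$dup_other_hi)) return("DUP")
  if (in_band(mean_b, th$dup_lo, th$dup_hi) &&
      in_band(mean_a, th$dup_other_lo, th$dup_other_hi)) return("DUP")
  "NORMAL"
}

#' Call per-marker zygosity and copy states
#'
#' For each marker the Watson and Crick probe ratios are averaged per allele;
#' a marker is HET when both allele means fall in the heterozygous band,
#' HOM_A/HOM_B when the matching allele mean clears \code{hom_match_min} and
#' the other falls below \code{hom_mismatch_max}, and AMBIGUOUS otherwise.
#' A secondary, independent pass flags copy states (DEL/DUP bands); zygosity
#' is never conditioned on it. Markers with missing probes are AMBIGUOUS and
#' flagged.
#'
#' @param map a \code{snp_map}.
#' @param probe_table normalized probe table (see \code{normalize_ratios}).
#' @param thresholds a \code{call_thresholds}.
#' @return data.frame with chrom, coord, mean_a, mean_b, state, copy_state,
#'   missing_probe.
#' @export
call_genotypes <- function(map, probe_table, thresholds = call_thresholds()) {
  if (!"ratio" %in% names(probe_table))
    probe_table <- normalize_ratios(probe_table)
  ratio <- probe_table$ratio
  names(ratio) <- probe_table$probe_id
  ra <- cbind(ratio[map$probe_aw], ratio[map$probe_ac])
  rb <- cbind(ratio[map$probe_bw], ratio[map$probe_bc])
  mean_a <- rowMeans(ra, na.rm = TRUE)
  mean_b <- rowMeans(rb, na.rm = TRUE)
  missing <- is.na(ra[, 1]) | is.na(ra[, 2]) | is.na(rb[, 1]) | is.na(rb[, 2])
  mean_a[is.nan(mean_a)] <- NA
  mean_b[is.nan(mean_b)] <- NA
  n <- nrow(map)
  th <- thresholds
  tt <- function(x) !is.na(x) & x  # NA-safe condition
  in_het_a <- tt(mean_a >= th$het_lo & mean_a <= th$het_hi)
  in_het_b <- tt(mean_b >= th$het_lo & mean_b <= th$het_hi)
  state <- rep("AMBIGUOUS", n)
  state[in_het_a & in_het_b] <- "HET"
  state[tt(mean_a >= th$hom_match_min & mean_b <= th$hom_mismatch_max)] <- "HOM_A"
  state[tt(mean_b >= th$hom_match_min & mean_a <= th$hom_mismatch_max)] <- "HOM_B"
  state[missing] <- "AMBIGUOUS"
  in_dup_a <- tt(mean_a >= th$dup_lo & mean_a <= th$dup_hi)
  in_dup_b <- tt(mean_b >= th$dup_lo & mean_b <= th$dup_hi)
  in_oth_a <- tt(mean_a >= th$dup_other_lo & mean_a <= th$dup_other_hi)
  in_oth_b <- tt(mean_b >= th$dup_other_lo & mean_b <= th$dup_other_hi)
  copy <- rep("NORMAL", n)
  copy[(in_dup_a & in_oth_b) | (in_dup_b & in_oth_a)] <- "DUP"
  copy[(in_het_a & tt(mean_b <= th$del_max)) |
       (in_het_b & tt(mean_a <= th$del_max))] <- "DEL"
  data.frame(chrom = map$chrom, coord = map$coord,
             mean_a = unname(mean_a), mean_b = unname(mean_b),
             state = state, copy_state = copy,
             missing_probe = missing, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Resolve AMBIGUOUS calls by neighbourhood majority
#'
#' Each AMBIGUOUS marker takes the majority zygosity state of the
#' \code{window} nearest non-ambiguous markers on its chromosome (ties go to
#' the nearer neighbours). Markers are never re-thresholded. Chromosomes with
#' no unambiguous marker are left unchanged.
#'
#' @param calls output of \code{call_genotypes}, coordinate-sorted.
#' @param window neighbourhood size (default 5).
#' @return calls with AMBIGUOUS states replaced where resolvable.
#' @export
resolve_ambiguous <- function(calls, window = 5) {
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    st <- calls$state[idx]
    amb <- which(st == "AMBIGUOUS")
    good <- which(st != "AMBIGUOUS")
    if (length(amb) == 0 || length(good) == 0) next
    for (j in amb) {
      nb <- good[order(abs(good - j))][seq_len(min(window, length(good)))]
      tab <- sort(table(st[nb]), decreasing = TRUE)
      st[j] <- names(tab)[1]
    }
    calls$state[idx] <- st
  }
  calls
}

#' Sliding-window smoothing of a marker track for display
#'
#' Moving mean over \code{window} adjacent markers within each chromosome
#' (centred; window truncated at chromosome ends). Intended for plotted
#' hybridization tracks only -- genotype calling never uses smoothed values.
#' If a chromosome carries fewer markers than \code{window}, its values are
#' replaced by the chromosome-wide mean, with a warning.
#'
#' @param values numeric vector (e.g. per-marker mean ratios).
#' @param chrom chromosome of each marker (same length as \code{values}).
#' @param window window size in markers (default 10).
#' @return numeric vector of smoothed values.
#' @export
smooth_track <- function(values, chrom, window = 10) {
  out <- numeric(length(values))
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1 - half_lo
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    v <- values[idx]
    n <- length(v)
    if (n < window) {
      warning("window (", window, ") exceeds markers on ", ch,
              "; using chromosome-wide mean")
      out[idx] <- mean(v)
      next
    }
    cs <- cumsum(c(0, v))
    lo <- pmax(1, seq_len(n) - half_lo)
    hi <- pmin(n, seq_len(n) + half_hi)
    out[idx] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  out
}
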