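# Absorb runs shorter than min_markers into a flanking run. When both flanks
# exist the run joins the flank with more markers; ties go to the preceding
# (left, coordinate-proximal) run. Returns the smoothed per-marker states.
absorb_runs <- function(states, min_markers = 2) {
  repeat {
    r <- rle(states)
    if (length(r$lengths) <= 1) return(states)
    short <- which(r$lengths < min_markers)
    if (length(short) == 0) return(states)
    i <- short[which.min(r$lengths[short])]
    take <- if (i == 1) 2L
      else if (i == length(r$lengths)) i - 1L
      else if (r$lengths[i + 1] > r$lengths[i - 1]) i + 1L
      else i - 1L
    r$values[i] <- r$values[take]
    states <- inverse.rle(r)
  }
}

#' Segment per-marker calls into zygosity runs and transitions
#'
#' Builds maximal runs of constant zygosity state per chromosome. Runs
#' shorter than \code{min_markers} are absorbed into a flanking run first
#' (single-marker states at array resolution are indistinguishable from
#' noise). Every state change yields a transition carrying both boundary
#' marker coordinates: the last marker of the preceding state and the first
#' marker of the following state.
#'
#' @param calls coordinate-sorted calls (see \code{call_genotypes}); AMBIGUOUS
#'   states should already be majority-resolved.
#' @param min_markers minimum run length in markers (default 2).
#' @param sample_id sample identifier stamped on the segments.
#' @param state_col column of \code{calls} holding the state to segment.
#' @return list with \code{segments} (sample_id, chrom, start_coord,
#'   end_coord, state, n_markers) and \code{transitions} (chrom, proximal,
#'   distal, state_from, state_to).
#' @export
segment_calls <- function(calls, min_markers = 2, sample_id = "sample",
                          state_col = "state") {
  seg_list <- list()
  tr_list <- list()
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    if (length(idx) == 0) {
      warning("no markers on ", ch)
      next
    }
    st <- absorb_runs(calls[[state_col]][idx], min_markers)
    co <- calls$coord[idx]
    r <- rle(st)
    ends <- cumsum(r$lengths)
    starts <- c(1, head(ends, -1) + 1)
    seg_list[[ch]] <- data.frame(
      sample_id = sample_id, chrom = ch,
      start_coord = co[starts], end_coord = co[ends],
      state = r$values, n_markers = r$lengths, stringsAsFactors = FALSE)
    if (length(r$values) > 1) {
      k <- seq_len(length(r$values) - 1)
      tr_list[[ch]] <- data.frame(
        chrom = ch, proximal = co[ends[k]], distal = co[starts[k + 1]],
        state_from = r$values[k], state_to = r$values[k + 1],
        stringsAsFactors = FALSE)
    }
  }
  empty_tr <- data.frame(chrom = character(0), proximal = numeric(0),
                         distal = numeric(0), state_from = character(0),
                         state_to = character(0), stringsAsFactors = FALSE)
  list(segments = do.call(rbind, c(seg_list, make.row.names = FALSE)),
       transitions = if (length(tr_list)) do.call(rbind, c(tr_list, make.row.names = FALSE)) else empty_tr)
}

# chromatid contribution of a sector zygosity state
state_counts <- function(state) {
  switch(state,
    HET = c(1L, 1L), HOM_A = c(2L, 0L), HOM_B = c(0L, 2L),
    c(NA_integer_, NA_integer_))
}

region_label <- function(n_a, n_b) {
  if (is.na(n_a) || is.na(n_b)) return(NA_character_)
  if (n_a == 2 && n_b == 2) return("2:2")
  if (n_a == 3) return("3:1A")
  if (n_b == 3) return("3:1B")
  if (n_a == 4) return("4:0A")
  if (n_b == 4) return("4:0B")
  NA_character_
}

#' Pair red and white sector calls into four-chromatid allele counts
#'
#' The two sectors of a red/white colony each hold two of the four chromatids
#' of the cell that divided: region-wise allele counts across the sector pair
#' reveal the conversion structure. Each chromosome is partitioned at the
#' union of both sectors' state changes; every region is annotated with the
#' combined A:B count (HET+HET gives 2:2, HOM_B+HET 3:1B, HOM_B+HOM_B 4:0B,
#' and so on). The partition covers each chromosome exactly once.
#'
#' @param red_calls,white_calls resolved calls on the same marker map.
#' @param min_markers run-absorption threshold passed to segmentation.
#' @return data.frame with chrom, start_coord, end_coord, n_markers,
#'   red_state, white_state, label.
#' @export
pair_sectors <- function(red_calls, white_calls, min_markers = 2) {
  if (nrow(red_calls) != nrow(white_calls) ||
      !all(red_calls$chrom == white_calls$chrom &
           red_calls$coord == white_calls$coord))
    stop("sectors use different marker maps")
  out <- list()
  for (ch in unique(red_calls$chrom)) {
    idx <- which(red_calls$chrom == ch)
    rs <- absorb_runs(red_calls$state[idx], min_markers)
    ws <- absorb_runs(white_calls$state[idx], min_markers)
    co <- red_calls$coord[idx]
    joint <- paste(rs, ws, sep = "|")
    r <- rle(joint)
    ends <- cumsum(r$lengths)
    starts <- c(1, head(ends, -1) + 1)
    pieces <- strsplit(r$values, "|", fixed = TRUE)
    lab <- vapply(pieces, function(p) {
      cr <- state_counts(p[1]); cw <- state_counts(p[2])
      region_label(cr[1] + cw[1], cr[2] + cw[2])
    }, "")
    out[[ch]] <- data.frame(
      chrom = ch, start_coord = co[starts], end_coord = co[ends],
      n_markers = r$lengths,
      red_state = vapply(pieces, `[`, "", 1),
      white_state = vapply(pieces, `[`, "", 2),
      label = lab, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Classify a conversion-tract region sequence
#'
#' Applies the four-chromatid decision table to an ordered sequence of
#' regions at one event locus: NONE without any non-2:2 region; THREE_ONE /
#' FOUR_ZERO for exactly one such region; HYBRID for a contiguous block of
#' one 4:0 region plus same-donor 3:1 region(s); COMPLEX otherwise (two or
#' more disjoint non-2:2 regions, or donor switching). The lesion origin is
#' DSCB whenever any 4:0 region is present (both sister chromatids must have
#' been broken), SCB when only single-donor 3:1 regions are seen, and
#' UNCLASSIFIED for mixed-donor tracts without a 4:0 region. Non-2:2 regions
#' shorter than \code{min_markers} markers are disregarded.
#'
#' @param regions region data.frame from \code{pair_sectors} (one locus).
#' @param min_markers minimum markers for a region to count (default 2).
#' @return list with tract_class, origin, conv_lo, conv_hi (outermost
#'   converted marker coordinates; NA when class is NONE) and n_regions.
#' @export
classify_tract <- function(regions, min_markers = 2) {
  lab <- regions$label
  conv <- !is.na(lab) & lab != "2:2" & regions$n_markers >= min_markers
  none <- list(tract_class = "NONE", origin = "NONE",
               conv_lo = NA_real_, conv_hi = NA_real_, n_regions = 0L)
  if (!any(conv)) return(none)
  keep <- regions[conv, , drop = FALSE]
  kinds <- substr(keep$label, 1, 3)
  donors <- substr(keep$label, 4, 4)
  has40 <- any(kinds == "4:0")
  origin <- if (has40) "DSCB"
    else if (length(unique(donors)) == 1) "SCB"
    else "UNCLASSIFIED"
  conv_idx <- which(conv)
  contiguous <- all(diff(conv_idx) == 1)
  n40 <- sum(kinds == "4:0")
  tract_class <- if (nrow(keep) == 1) {
    if (has40) "FOUR_ZERO" else "THREE_ONE"
  } else if (contiguous && n40 == 1 && all(kinds[kinds != "4:0"] == "3:1") &&
             length(unique(donors)) == 1) {
    "HYBRID"
  } else "COMPLEX"
  list(tract_class = tract_class, origin = origin,
       conv_lo = min(keep$start_coord), conv_hi = max(keep$end_coord),
       n_regions = nrow(keep))
}

#' Conversion-tract length
#'
#' Tract length is the average of the maximum length (distance between the
#' nearest flanking markers NOT included in the tract) and the minimum length
#' (distance between the outermost converted markers). When the tract reaches
#' a chromosome end without a flanking marker, the maximum bound is clipped
#' to the chromosome end (or the tract bound itself if no length is known)
#' and the result flagged.
#'
#' @param chrom chromosome of the tract.
#' @param conv_lo,conv_hi outermost converted marker coordinates.
#' @param map the marker map.
#' @param chrom_length optional chromosome length for clipping.
#' @return list with min_len, max_len, length, clipped.
#' @export
tract_length <- function(chrom, conv_lo, conv_hi, map, chrom_length = NULL) {
  mk <- map$coord[map$chrom == chrom]
  below <- mk[mk < conv_lo]
  above <- mk[mk > conv_hi]
  clipped <- FALSE
  flank_lo <- if (length(below)) max(below) else {
    clipped <- TRUE
    if (!is.null(chrom_length)) 1 else conv_lo
  }
  flank_hi <- if (length(above)) min(above) else {
    clipped <- TRUE
    if (!is.null(chrom_length)) chrom_length else conv_hi
  }
  min_len <- conv_hi - conv_lo
  max_len <- flank_hi - flank_lo
  list(min_len = min_len, max_len = max_len,
       length = (min_len + max_len) / 2, clipped = clipped)
}

empty_events <- function() {
  data.frame(event_id = character(0), sample_id = character(0),
             type = character(0), chrom = character(0),
             gaining_haplotype = character(0),
             t1_proximal = numeric(0), t1_distal = numeric(0),
             t2_proximal = numeric(0), t2_distal = numeric(0),
             hom_boundary = numeric(0), tract_class = character(0),
             origin = character(0), min_len = numeric(0),
             max_len = numeric(0), length = numeric(0),
             stringsAsFactors = FALSE)
}

event_row <- function(sample_id, type, chrom, gaining = NA, t1p = NA, t1d = NA,
                      t2p = NA, t2d = NA, hom_boundary = NA,
                      tract_class = NA, origin = NA,
                      min_len = NA, max_len = NA, length = NA) {
  data.frame(event_id = NA_character_, sample_id = sample_id, type = type,
             chrom = chrom, gaining_haplotype = gaining,
             t1_proximal = t1p, t1_distal = t1d,
             t2_proximal = t2p, t2_distal = t2d, hom_boundary = hom_boundary,
             tract_class = tract_class, origin = origin,
             min_len = min_len, max_len = max_len, length = length,
             stringsAsFactors = FALSE)
}

#' Classify the unselected genomic alterations of one sample
#'
#' Scans zygosity and copy-state segments of a single sector or isolate:
#' an LOH run touching a chromosome-end marker is a terminal BIR-or-crossover
#' event (the two are indistinguishable from a single sector); an internal
#' LOH run is an interstitial gene conversion; terminal copy-gain/loss runs
#' are terminal duplications/deletions; a copy-gain spanning the whole
#' chromosome is a trisomy candidate. Crossover association of interstitial
#' conversions is deliberately not inferred. Tract lengths are computed for
#' interstitial conversions.
#'
#' @param calls resolved calls for one sample.
#' @param map the marker map.
#' @param chrom_lengths named chromosome lengths (for clipping).
#' @param sample_id sample identifier.
#' @param min_markers run-absorption threshold.
#' @param trisomy_frac fraction of a chromosome's markers that must be
#'   copy-gain to call a trisomy (default 0.5).
#' @return events data.frame (one row per event).
#' @export
classify_unselected_events <- function(calls, map, chrom_lengths = NULL,
                                       sample_id = "sample", min_markers = 2,
                                       trisomy_frac = 0.5) {
  zyg <- segment_calls(calls, min_markers, sample_id)$segments
  cp <- segment_calls(calls, min_markers, sample_id,
                      state_col = "copy_state")$segments
  events <- list()
  for (ch in unique(calls$chrom)) {
    mk <- calls$coord[calls$chrom == ch]
    first_mk <- mk[1]; last_mk <- mk[length(mk)]
    zch <- zyg[zyg$chrom == ch, , drop = FALSE]
    # LOH runs
    for (i in which(zch$state %in% c("HOM_A", "HOM_B"))) {
      s <- zch[i, ]
      gaining <- if (s$state == "HOM_A") "A" else "B"
      left_term <- s$start_coord == first_mk
      right_term <- s$end_coord == last_mk
      prev_mk <- if (!left_term) max(mk[mk < s$start_coord]) else NA
      next_mk <- if (!right_term) min(mk[mk > s$end_coord]) else NA
      if (left_term && right_term) {
        # whole-chromosome LOH: report as terminal (UPD-like), no transitions
        events[[length(events) + 1]] <- event_row(
          sample_id, "BIR_OR_CO_TERMINAL", ch, gaining,
          t2p = last_mk, t2d = last_mk, hom_boundary = s$start_coord)
      } else if (left_term) {
        events[[length(events) + 1]] <- event_row(
          sample_id, "BIR_OR_CO_TERMINAL", ch, gaining,
          t1p = s$end_coord, t1d = next_mk,
          t2p = first_mk, t2d = first_mk, hom_boundary = s$end_coord)
      } else if (right_term) {
        events[[length(events) + 1]] <- event_row(
          sample_id, "BIR_OR_CO_TERMINAL", ch, gaining,
          t1p = prev_mk, t1d = s$start_coord,
          t2p = last_mk, t2d = last_mk, hom_boundary = s$start_coord)
      } else {
        tl <- tract_length(ch, s$start_coord, s$end_coord, map,
                           chrom_length = chrom_lengths[[ch]])
        events[[length(events) + 1]] <- event_row(
          sample_id, "GC_INTERSTITIAL", ch, gaining,
          t1p = prev_mk, t1d = s$start_coord,
          t2p = s$end_coord, t2d = next_mk,
          min_len = tl$min_len, max_len = tl$max_len, length = tl$length)
      }
    }
    # copy-state runs
    cch <- cp[cp$chrom == ch, , drop = FALSE]
    n_mk <- length(mk)
    dup_rows <- cch$state == "DUP"
    dup_markers <- sum(cch$n_markers[dup_rows])
    # trisomy: copy gain over most of the chromosome AND reaching both ends
    # (a large terminal duplication reaches only one)
    dup_both_ends <- any(dup_rows & cch$start_coord == first_mk) &&
      any(dup_rows & cch$end_coord == last_mk)
    if (dup_markers >= trisomy_frac * n_mk && dup_both_ends) {
      events[[length(events) + 1]] <- event_row(
        sample_id, "TRISOMY", ch,
        t1p = first_mk, t1d = first_mk, t2p = last_mk, t2d = last_mk)
      next
    }
    for (i in which(cch$state %in% c("DUP", "DEL"))) {
      s <- cch[i, ]
      type <- if (s$state == "DUP") "TERMINAL_DUP" else "TERMINAL_DEL"
      left_term <- s$start_coord == first_mk
      right_term <- s$end_coord == last_mk
      if (!left_term && !right_term) next  # interstitial CNV: not modelled
      if (left_term) {
        next_mk <- if (s$end_coord < last_mk) min(mk[mk > s$end_coord]) else last_mk
        events[[length(events) + 1]] <- event_row(
          sample_id, type, ch,
          t1p = s$end_coord, t1d = next_mk,
          t2p = first_mk, t2d = first_mk, hom_boundary = s$end_coord)
      } else {
        prev_mk <- if (s$start_coord > first_mk) max(mk[mk < s$start_coord]) else first_mk
        events[[length(events) + 1]] <- event_row(
          sample_id, type, ch,
          t1p = prev_mk, t1d = s$start_coord,
          t2p = last_mk, t2d = last_mk, hom_boundary = s$start_coord)
      }
    }
  }
  if (length(events) == 0) return(empty_events())
  out <- do.call(rbind, c(events, make.row.names = FALSE))
  out$event_id <- paste0(sample_id, "_ev", seq_len(nrow(out)))
  out
}

#' Detect and classify the selected crossover of a sectored colony
#'
#' Confirms reciprocal terminal LOH on the chromosome V left arm covering the
#' selection locus -- the red sector homozygous for haplotype A and the white
#' sector for haplotype B at the marker nearest the locus -- then extracts the
#' associated conversion-tract region sequence from the paired sectors,
#' classifies it and measures its length.
#'
#' @param red_calls,white_calls resolved calls for the two sectors.
#' @param map the marker map.
#' @param sel_locus selection-locus coordinate on chrV (default 32000).
#' @param centromere centromere coordinate on chrV (default 152000).
#' @param min_markers region threshold.
#' @param chrom_length chrV length for tract clipping.
#' @return list with \code{selected} (logical), \code{event} (one-row events
#'   data.frame, or NULL on selection failure) and \code{regions} (chrV
#'   region table).
#' @export
detect_selected_crossover <- function(red_calls, white_calls, map,
                                      sel_locus = 32000, centromere = 152000,
                                      min_markers = 2, chrom_length = NULL) {
  rV <- red_calls[red_calls$chrom == "chrV", , drop = FALSE]
  wV <- white_calls[white_calls$chrom == "chrV", , drop = FALSE]
  if (nrow(rV) == 0) stop("no chrV markers")
  sel_idx <- which.min(abs(rV$coord - sel_locus))
  rs <- absorb_runs(rV$state, min_markers)
  ws <- absorb_runs(wV$state, min_markers)
  if (!(rs[sel_idx] == "HOM_A" && ws[sel_idx] == "HOM_B"))
    return(list(selected = FALSE, event = NULL, regions = NULL))
  regions <- pair_sectors(rV, wV, min_markers)
  left <- regions
  cl <- classify_tract(left, min_markers)
  # crossover breakpoint transition: end of the reciprocal-LOH block
  recip <- which(left$red_state == "HOM_A" & left$white_state == "HOM_B")
  if (length(recip) == 0)
    return(list(selected = FALSE, event = NULL, regions = regions))
  bp_region <- max(recip)
  t1p <- left$end_coord[bp_region]
  t1d <- if (bp_region < nrow(left)) left$start_coord[bp_region + 1] else NA
  if (cl$tract_class == "NONE") {
    ev <- event_row("colony", "CO", "chrV", gaining = NA,
                    t1p = t1p, t1d = t1d, hom_boundary = t1p,
                    tract_class = "NONE", origin = "NONE")
  } else {
    tl <- tract_length("chrV", cl$conv_lo, cl$conv_hi, map, chrom_length)
    ev <- event_row("colony", "CO", "chrV", gaining = NA,
                    t1p = t1p, t1d = t1d, hom_boundary = t1p,
                    tract_class = cl$tract_class, origin = cl$origin,
                    min_len = tl$min_len, max_len = tl$max_len,
                    length = tl$length)
  }
  ev$event_id <- "selected_co"
  list(selected = TRUE, event = ev, regions = regions)
}
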