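#' Saccharomyces cerevisiae chromosome lengths (SGD R64, bp)
#' @keywords internal
yeast_chrom_lengths <- function() {
  c(chrI = 230218, chrII = 813184, chrIII = 316620, chrIV = 1531933,
    chrV = 576874, chrVI = 270161, chrVII = 1090940, chrVIII = 562643,
    chrIX = 439888, chrX = 745751, chrXI = 666816, chrXII = 1078177,
    chrXIII = 924431, chrXIV = 784333, chrXV = 1091291, chrXVI = 948066)
}

#' Simulation configuration
#'
#' Bundles every tunable quantity of the diploid recombination simulator.
#' Defaults describe a W303-1A x YJM789-style hybrid diploid assayed on a
#' whole-genome SNP array: ~13,000 markers over 16 chromosomes with ~750 on
#' the 577-kb chromosome V, a selectable crossover interval on the chromosome
#' V left arm (selection locus at 32 kb, centromere near 152 kb), heterozygous
#' probe ratios near 1, homozygous-matching near 1.5 and homozygous-mismatching
#' near 0.25, multiplicative lognormal noise, and recombination events whose
#' lesion origin is a double-sister-chromatid break (DSCB) with probability
#' \code{dscb_fraction} and whose conversion-tract lengths are lognormal with
#' medians 18.2 kb (DSCB) and 7.9 kb (SCB).
#'
#' @param n_markers total marker count genome-wide (chromosome V share fixed).
#' @param n_markers_chrV markers on chromosome V.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param analyzed_bp genome size represented on the array, per isolate.
#' @param sel_locus,centromere_V chromosome V selection-locus and centromere
#'   coordinates (bp) bounding the selected crossover interval.
#' @param dscb_fraction probability a conversion-bearing crossover is DSCB.
#' @param p_no_conversion probability a selected crossover has no tract.
#' @param p_equal_tracts probability the two DSCB tracts have equal length
#'   (pure 4:0 rather than 4:0/3:1 hybrid).
#' @param p_complex probability extra heterozygous interruptions ("patchy"
#'   repair) are punched into a conversion tract.
#' @param tract_median_dscb,tract_median_scb lognormal tract-length medians, bp.
#' @param tract_sdlog_dscb,tract_sdlog_scb lognormal sdlog parameters.
#' @param ratio_het,ratio_hom_match,ratio_hom_mismatch per-probe ratio means.
#' @param ratio_dup_gain,ratio_dup_other,ratio_del_lost,ratio_del_kept probe
#'   ratio means for copy-gain and copy-loss states (tunable constants; the
#'   assay literature reports no canonical values for these states).
#' @param noise_sd sd of the lognormal multiplicative noise (log scale).
#' @param ctrl_intensity control-channel scale constant.
#' @param unselected_rate mean unselected LOH events per sectored colony.
#' @param mixture named weights over unselected event types (must sum to 1).
#' @param min_tract_markers minimum markers a simulated tract must span.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_markers = 13000,
                       n_markers_chrV = 750,
                       chrom_lengths = yeast_chrom_lengths(),
                       analyzed_bp = 11.6e6,
                       sel_locus = 32000,
                       centromere_V = 152000,
                       dscb_fraction = 0.75,
                       p_no_conversion = 1 / 43,
                       p_equal_tracts = 0.3,
                       p_complex = 0,
                       tract_median_dscb = 18200,
                       tract_median_scb = 7900,
                       tract_sdlog_dscb = 0.39,
                       tract_sdlog_scb = 1.05,
                       ratio_het = 1.0,
                       ratio_hom_match = 1.5,
                       ratio_hom_mismatch = 0.25,
                       ratio_dup_gain = 1.3,
                       ratio_dup_other = 0.8,
                       ratio_del_lost = 0.25,
                       ratio_del_kept = 1.0,
                       noise_sd = 0.1,
                       ctrl_intensity = 1000,
                       unselected_rate = 3,
                       mixture = c(GC_INTERSTITIAL = 0.62,
                                   BIR_OR_CO_TERMINAL = 0.31,
                                   TERMINAL_DUP = 0.03,
                                   TERMINAL_DEL = 0.03,
                                   TRISOMY = 0.01),
                       min_tract_markers = 2) {
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (dscb_fraction < 0 || dscb_fraction > 1) stop("dscb_fraction must be in [0,1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from YAML
#' @param path YAML file; keys are \code{sim_config} argument names.
#' @return a \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$chrom_lengths)) vals$chrom_lengths <- unlist(vals$chrom_lengths)
  if (!is.null(vals$mixture)) vals$mixture <- unlist(vals$mixture)
  do.call(sim_config, vals)
}

#' Simulate a SNP marker map
#'
#' Places markers uniformly at random within each chromosome: a fixed count on
#' chromosome V and the remainder allocated to the other chromosomes in
#' proportion to length. Probe identifiers encode chromosome, coordinate and
#' the allele/strand of the oligo.
#'
#' @param config a \code{sim_config}.
#' @param seed integer seed.
#' @return a \code{snp_map} data.frame.
#' @export
simulate_snp_map <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  lens <- config$chrom_lengths
  others <- setdiff(names(lens), "chrV")
  n_other <- config$n_markers - config$n_markers_chrV
  alloc <- round(n_other * lens[others] / sum(lens[others]))
  alloc["chrV"] <- config$n_markers_chrV
  alloc <- alloc[names(lens)]
  rows <- lapply(names(lens), function(ch) {
    coords <- sort(sample.int(lens[[ch]] - 2L, alloc[[ch]]) + 1L)
    data.frame(chrom = ch, coord = coords, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  key <- paste0(map$chrom, "_", map$coord)
  map$allele_a_id <- paste0(key, "_A")
  map$allele_b_id <- paste0(key, "_B")
  map$probe_aw <- paste0(key, "_AW")
  map$probe_ac <- paste0(key, "_AC")
  map$probe_bw <- paste0(key, "_BW")
  map$probe_bc <- paste0(key, "_BC")
  validate_snp_map(map)
}

# A chromatid track records, per marker, how many of the cell's chromosome
# copies carry each parental haplotype (n_a, n_b). The unrecombined diploid
# is (1, 1) everywhere; LOH gives (2, 0)/(0, 2); copy-number states use
# (1, 0), (2, 1), etc.
new_track <- function(map) {
  data.frame(chrom = map$chrom, coord = map$coord,
             n_a = 1L, n_b = 1L, stringsAsFactors = FALSE)
}

draw_tract_len <- function(config, origin, n = 1) {
  med <- if (origin == "DSCB") config$tract_median_dscb else config$tract_median_scb
  sdl <- if (origin == "DSCB") config$tract_sdlog_dscb else config$tract_sdlog_scb
  stats::rlnorm(n, meanlog = log(med), sdlog = sdl)
}

# set haplotype counts over a coordinate interval (inclusive)
set_region <- function(track, chrom, lo, hi, n_a, n_b) {
  i <- track$chrom == chrom & track$coord >= lo & track$coord <= hi
  track$n_a[i] <- n_a
  track$n_b[i] <- n_b
  track
}

# punch 1-2 heterozygous interruptions into [lo, hi] on the given tracks;
# returns list(tracks, holes)
punch_holes <- function(tracks, chrom, lo, hi, map) {
  span <- hi - lo
  n_holes <- sample(1:2, 1)
  holes <- list()
  for (k in seq_len(n_holes)) {
    h_lo <- lo + stats::runif(1, 0.15, 0.7) * span
    h_hi <- min(hi - 1, h_lo + stats::runif(1, 0.05, 0.2) * span)
    mk <- map$coord[map$chrom == chrom & map$coord >= h_lo & map$coord <= h_hi]
    if (length(mk) < 2) next  # hole must be visible at marker resolution
    tracks <- lapply(tracks, set_region, chrom = chrom, lo = h_lo, hi = h_hi,
                     n_a = 1L, n_b = 1L)
    holes[[length(holes) + 1]] <- c(h_lo, h_hi)
  }
  list(tracks = tracks, holes = holes)
}

#' Simulate a red/white sectored colony
#'
#' Imprints a selected reciprocal crossover on the chromosome V left arm --
#' the red sector becomes homozygous for the A (W303-1A-like) haplotype distal
#' to the breakpoint and the white sector homozygous for B -- together with
#' its associated gene-conversion tract: an SCB event leaves a 3:1 region in
#' one sector; a DSCB event leaves a 4:0 region (equal tracts) or a 4:0/3:1
#' hybrid (unequal tracts) across the sector pair. Unselected events are added
#' independently per the configured type mixture (on chromosomes other than V,
#' so they never confound the selected event).
#'
#' @param config a \code{sim_config}.
#' @param seed integer seed.
#' @param map optional pre-built marker map (rebuilt from \code{seed} if NULL).
#' @param colony_id sample identifier prefix.
#' @return list with elements \code{red}, \code{white} (chromatid tracks),
#'   \code{truth} (ground-truth event table) and \code{map}.
#' @export
simulate_sectored_colony <- function(config = sim_config(), seed = 1,
                                     map = NULL, colony_id = "colony1") {
  if (is.null(map)) map <- simulate_snp_map(config, seed = seed)
  set.seed(seed + 1L)
  mkV <- map$coord[map$chrom == "chrV"]
  lenV <- config$chrom_lengths[["chrV"]]
  sel_zone <- mkV[mkV > config$sel_locus + 2000 & mkV < config$centromere_V - 2000]
  if (length(sel_zone) == 0)
    stop("no markers available in the selected-crossover interval")
  red <- new_track(map)
  white <- new_track(map)

  b <- sample(sel_zone, 1)  # crossover breakpoint (marker coordinate)
  donor <- sample(c("A", "B"), 1)  # intact homolog donating sequence
  is_dscb <- stats::runif(1) < config$dscb_fraction
  no_conv <- stats::runif(1) < config$p_no_conversion

  # reciprocal LOH distal (telomere side) of the breakpoint
  red <- set_region(red, "chrV", 1, b, 2L, 0L)
  white <- set_region(white, "chrV", 1, b, 0L, 2L)

  tract_hi <- NA_real_
  tract_class <- "NONE"
  origin <- NA_character_
  if (!no_conv) {
    origin <- if (is_dscb) "DSCB" else "SCB"
    if (is_dscb) {
      # the measurable DSCB tract is the union of both chromatids' conversion
      # tracts: draw its full extent, then place the shorter tract inside it
      L2 <- draw_tract_len(config, "DSCB")
      L1 <- if (stats::runif(1) < config$p_equal_tracts) L2
        else stats::runif(1, 0.2, 0.9) * L2
      L <- c(L1, L2)
      # both chromatids of the broken homolog converted over [b, b+L1];
      # the longer tract extends the conversion on one chromatid to b+L2
      if (donor == "B") {
        red <- set_region(red, "chrV", b + 1, b + L[1], 0L, 2L)
        white <- set_region(white, "chrV", 1, b + L[2], 0L, 2L)
      } else {
        white <- set_region(white, "chrV", b + 1, b + L[1], 2L, 0L)
        red <- set_region(red, "chrV", 1, b + L[2], 2L, 0L)
      }
      # visibility at marker resolution: a region needs >= min_tract_markers
      # markers to be distinguishable (the classifier applies the same rule)
      mtm <- config$min_tract_markers
      vis41 <- sum(mkV > b & mkV <= b + L[1]) >= mtm
      vis31 <- L[1] < L[2] && sum(mkV > b + L[1] & mkV <= b + L[2]) >= mtm
      tract_class <- if (vis41 && vis31) "HYBRID"
        else if (vis41) "FOUR_ZERO"
        else if (vis31) "THREE_ONE"
        else "NONE"
      tract_hi <- b + L[2]
    } else {
      L <- draw_tract_len(config, "SCB")
      # one broken chromatid converted by the donor homolog
      if (donor == "B") white <- set_region(white, "chrV", 1, b + L, 0L, 2L)
      else red <- set_region(red, "chrV", 1, b + L, 2L, 0L)
      tract_class <- if (sum(mkV > b & mkV <= b + L) >= config$min_tract_markers)
        "THREE_ONE" else "NONE"
      tract_hi <- b + L
    }
    if (tract_class == "NONE") origin <- NA_character_
    # patchy repair: heterozygous interruptions inside the tract
    if (tract_class != "NONE" && stats::runif(1) < config$p_complex) {
      conv <- if (donor == "B") {
        if (is_dscb) list(red = red, white = white) else list(white = white)
      } else {
        if (is_dscb) list(red = red, white = white) else list(red = red)
      }
      ph <- punch_holes(conv, "chrV", b + 1, tract_hi, map)
      if (length(ph$holes) > 0) {
        for (nm in names(ph$tracks)) assign(nm, ph$tracks[[nm]])
        tract_class <- "COMPLEX"
      }
    }
  }

  truth <- data.frame(
    sample_id = colony_id, type = "SELECTED_CO", chrom = "chrV",
    breakpoint = b, tract_lo = b,
    tract_hi = if (is.na(tract_hi)) b else tract_hi,
    tract_class = tract_class, origin = if (is.na(origin)) "NONE" else origin,
    donor = donor, stringsAsFactors = FALSE)

  # unselected events, assigned to one sector each
  n_uns <- stats::rpois(1, config$unselected_rate)
  if (n_uns > 0) {
    for (k in seq_len(n_uns)) {
      sector <- sample(c("red", "white"), 1)
      trk <- if (sector == "red") red else white
      res <- add_unselected_event(trk, map, config,
                                  exclude_chroms = "chrV",
                                  sample_id = paste0(colony_id, ".", sector))
      if (is.null(res)) next
      if (sector == "red") red <- res$track else white <- res$track
      truth <- rbind(truth, res$truth)
    }
  }
  list(red = red, white = white, truth = truth, map = map)
}

# place one unselected event on the track, avoiding existing non-parental
# regions; returns NULL if no placement found
add_unselected_event <- function(track, map, config, exclude_chroms = character(0),
                                 sample_id = "isolate", max_try = 50) {
  type <- sample(names(config$mixture), 1, prob = config$mixture)
  chroms <- setdiff(names(config$chrom_lengths), exclude_chroms)
  for (try in seq_len(max_try)) {
    ch <- sample(chroms, 1)
    len <- config$chrom_lengths[[ch]]
    mk <- map$coord[map$chrom == ch]
    if (type == "TRISOMY") {
      lo <- 1; hi <- len
    } else if (type == "GC_INTERSTITIAL") {
      origin <- if (stats::runif(1) < config$dscb_fraction) "DSCB" else "SCB"
      L <- draw_tract_len(config, origin)
      if (L >= len - 2) next  # tract longer than the chromosome: redraw
      lo <- stats::runif(1, 1, len - L)
      hi <- lo + L
      if (sum(mk >= lo & mk <= hi) < config$min_tract_markers) next
      # interstitial events need resolvable heterozygous flanks: at least
      # min_tract_markers markers on each side, or the flank run would be
      # absorbed and the event would read as terminal
      if (sum(mk < lo) < config$min_tract_markers ||
          sum(mk > hi) < config$min_tract_markers) next
    } else {  # terminal LOH / dup / del
      left_arm <- stats::runif(1) < 0.5
      bp <- stats::runif(1, 0.05 * len, 0.95 * len)
      lo <- if (left_arm) 1 else bp
      hi <- if (left_arm) bp else len
      if (sum(mk >= lo & mk <= hi) < config$min_tract_markers) next
      if (sum(mk < lo | mk > hi) < 1) next
    }
    i <- track$chrom == ch & track$coord >= lo & track$coord <= hi
    if (!all(track$n_a[i] == 1L & track$n_b[i] == 1L)) next  # overlap: retry
    gain <- sample(c("A", "B"), 1)
    counts <- switch(type,
      GC_INTERSTITIAL = ,
      BIR_OR_CO_TERMINAL = if (gain == "A") c(2L, 0L) else c(0L, 2L),
      TERMINAL_DUP = if (gain == "A") c(2L, 1L) else c(1L, 2L),
      TERMINAL_DEL = if (gain == "A") c(1L, 0L) else c(0L, 1L),
      TRISOMY = if (gain == "A") c(2L, 1L) else c(1L, 2L))
    track$n_a[i] <- counts[1]
    track$n_b[i] <- counts[2]
    truth <- data.frame(
      sample_id = sample_id, type = type, chrom = ch,
      breakpoint = lo, tract_lo = lo, tract_hi = hi,
      tract_class = "NONE", origin = "NONE", donor = gain,
      stringsAsFactors = FALSE)
    return(list(track = track, truth = truth))
  }
  NULL
}

#' Simulate a sub-cultured isolate
#'
#' Places exactly \code{n_events} non-overlapping unselected events (drawn
#' from the configured type mixture) uniformly over the marker-bearing genome
#' of a single diploid isolate.
#'
#' @param config a \code{sim_config}.
#' @param seed integer seed.
#' @param n_events number of events (default 10, the typical burden of a
#'   sub-cultured hyper-Rec isolate).
#' @param map optional pre-built marker map.
#' @param sample_id sample identifier.
#' @return list with \code{track}, \code{truth}, \code{map}.
#' @export
simulate_subcultured_isolate <- function(config = sim_config(), seed = 1,
                                         n_events = 10, map = NULL,
                                         sample_id = "isolate1") {
  if (n_events < 0) stop("n_events must be >= 0")
  if (is.null(map)) map <- simulate_snp_map(config, seed = seed)
  set.seed(seed + 2L)
  track <- new_track(map)
  truth <- NULL
  placed <- 0
  for (k in seq_len(n_events)) {
    res <- add_unselected_event(track, map, config, sample_id = sample_id)
    if (is.null(res))
      stop("could not place ", n_events, " non-overlapping events")
    track <- res$track
    truth <- rbind(truth, res$truth)
    placed <- placed + 1
  }
  if (is.null(truth)) truth <- data.frame(
    sample_id = character(0), type = character(0), chrom = character(0),
    breakpoint = numeric(0), tract_lo = numeric(0), tract_hi = numeric(0),
    tract_class = character(0), origin = character(0), donor = character(0),
    stringsAsFactors = FALSE)
  list(track = track, truth = truth, map = map)
}

# per-marker probe ratio means implied by the haplotype counts
state_ratio_means <- function(n_a, n_b, config) {
  key <- paste0(n_a, ":", n_b)
  ra <- rb <- rep(NA_real_, length(key))
  lut <- list(
    "1:1" = c(config$ratio_het, config$ratio_het),
    "2:0" = c(config$ratio_hom_match, config$ratio_hom_mismatch),
    "0:2" = c(config$ratio_hom_mismatch, config$ratio_hom_match),
    "1:0" = c(config$ratio_del_kept, config$ratio_del_lost),
    "0:1" = c(config$ratio_del_lost, config$ratio_del_kept),
    "2:1" = c(config$ratio_dup_gain, config$ratio_dup_other),
    "1:2" = c(config$ratio_dup_other, config$ratio_dup_gain))
  for (k in names(lut)) {
    i <- key == k
    ra[i] <- lut[[k]][1]
    rb[i] <- lut[[k]][2]
  }
  if (any(is.na(ra)))
    stop("unknown haplotype-count state: ", key[which(is.na(ra))[1]])
  list(ra = ra, rb = rb)
}

#' Render a chromatid track to a two-channel probe table
#'
#' Draws per-probe hybridization ratios around the state means implied by the
#' track's haplotype counts (heterozygous 1/1; homozygous 1.5 matching and
#' 0.25 mismatching; copy-loss 0.25 lost / 1.0 kept; copy-gain 1.3 gained /
#' 0.8 other), multiplied by lognormal noise, and converts them to
#' experimental/control channel intensities with the control channel fixed at
#' the configured scale constant.
#'
#' @param track a chromatid track (from the simulators).
#' @param map the marker map the track covers.
#' @param config a \code{sim_config}.
#' @param seed integer seed.
#' @return probe table data.frame (probe_id, exp_median, ctrl_median).
#' @export
render_probe_intensities <- function(track, map, config = sim_config(), seed = 1) {
  set.seed(seed + 3L)
  if (nrow(track) != nrow(map) ||
      !all(track$chrom == map$chrom & track$coord == map$coord))
    stop("track does not cover the marker map")
  means <- state_ratio_means(track$n_a, track$n_b, config)
  n <- nrow(map)
  noise <- function() if (config$noise_sd == 0) rep(1, n) else
    stats::rlnorm(n, 0, config$noise_sd)
  ratios <- c(means$ra * noise(), means$ra * noise(),
              means$rb * noise(), means$rb * noise())
  ids <- c(map$probe_aw, map$probe_ac, map$probe_bw, map$probe_bc)
  data.frame(probe_id = ids,
             exp_median = ratios * config$ctrl_intensity,
             ctrl_median = config$ctrl_intensity,
             stringsAsFactors = FALSE)
}
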