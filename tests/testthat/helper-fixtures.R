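# in-code fixtures shared across test files

# a minimal marker map: one or more chromosomes with given coordinate vectors
toy_map <- function(coords = list(chrV = seq(10, 100, by = 10))) {
  rows <- lapply(names(coords), function(ch) {
    key <- paste0(ch, "_", coords[[ch]])
    data.frame(chrom = ch, coord = coords[[ch]],
               allele_a_id = paste0(key, "_A"), allele_b_id = paste0(key, "_B"),
               probe_aw = paste0(key, "_AW"), probe_ac = paste0(key, "_AC"),
               probe_bw = paste0(key, "_BW"), probe_bc = paste0(key, "_BC"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# calls data.frame from a vector of zygosity states
toy_calls <- function(states, coords = NULL, chrom = "chrV",
                      copy_states = NULL) {
  n <- length(states)
  if (is.null(coords)) coords <- seq(10, by = 10, length.out = n)
  data.frame(chrom = chrom, coord = coords,
             mean_a = NA_real_, mean_b = NA_real_,
             state = states,
             copy_state = if (is.null(copy_states)) "NORMAL" else copy_states,
             missing_probe = FALSE, stringsAsFactors = FALSE)
}

# region table row for classify_tract tests
toy_regions <- function(labels, n_markers = 3) {
  n <- length(labels)
  start <- seq(1000, by = 5000, length.out = n)
  data.frame(chrom = "chrV", start_coord = start, end_coord = start + 4000,
             n_markers = rep_len(n_markers, n),
             red_state = "HET", white_state = "HET",
             label = labels, stringsAsFactors = FALSE)
}

# small config for fast simulations: ~40x fewer markers, 4 chromosomes
small_sim_config <- function(...) {
  sim_config(n_markers = 900, n_markers_chrV = 300,
             chrom_lengths = c(chrI = 230218, chrII = 813184,
                               chrV = 576874, chrXII = 1078177),
             ...)
}

# uniformly placed random elements over the genome
random_elements <- function(n, class_name, chrom_lengths, width = 300) {
  ch <- sample(names(chrom_lengths), n, TRUE,
               prob = chrom_lengths / sum(chrom_lengths))
  st <- floor(runif(n, 1, chrom_lengths[ch] - width - 1))
  data.frame(class_name = class_name, chrom = ch,
             start = st, end = st + width, stringsAsFactors = FALSE)
}

# the published 19-row association table used by the enrichment tests
element_table_path <- function() {
  system.file("extdata", "element_association_counts.tsv",
              package = "lohmapper")
}
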