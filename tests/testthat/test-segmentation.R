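test_that("segmentation yields maximal runs with both transition boundary coords", {
  calls <- toy_calls(c(rep("HET", 5), rep("HOM_A", 5)),
                     coords = seq(10, 100, by = 10))
  res <- segment_calls(calls)
  expect_equal(nrow(res$segments), 2)
  expect_equal(res$segments$n_markers, c(5, 5))
  expect_equal(res$transitions$proximal, 50)
  expect_equal(res$transitions$distal, 60)

  # single embedded call is absorbed at min_markers = 2
  calls2 <- toy_calls(c(rep("HET", 4), "HOM_A", rep("HET", 4)))
  res2 <- segment_calls(calls2, min_markers = 2)
  expect_equal(nrow(res2$segments), 1)
  expect_equal(nrow(res2$transitions), 0)

  # ties go to the preceding run
  calls3 <- toy_calls(c(rep("HET", 3), "HOM_A", rep("HOM_B", 3)))
  res3 <- segment_calls(calls3, min_markers = 2)
  expect_equal(res3$segments$state, c("HET", "HOM_B"))
  expect_equal(res3$segments$n_markers, c(4, 3))
})

test_that("sector pairing produces the canonical four-chromatid patterns", {
  coords <- seq(1000, 30000, by = 1000)
  n <- length(coords)
  b <- 10  # transition after marker 10

  # reciprocal CO, same boundary: 2:2 everywhere
  red <- toy_calls(c(rep("HOM_A", b), rep("HET", n - b)), coords)
  white <- toy_calls(c(rep("HOM_B", b), rep("HET", n - b)), coords)
  reg <- pair_sectors(red, white)
  expect_true(all(reg$label == "2:2"))

  # white HOM_B extends 12 markers past red's boundary: 3:1B region
  white2 <- toy_calls(c(rep("HOM_B", b + 12), rep("HET", n - b - 12)), coords)
  reg2 <- pair_sectors(red, white2)
  expect_equal(reg2$label, c("2:2", "3:1B", "2:2"))
  expect_equal(reg2$n_markers[2], 12)
  expect_equal(reg2$start_coord[2], coords[b + 1])

  # both sectors HOM_B over a shared span: 4:0B
  red3 <- toy_calls(c(rep("HOM_A", b), rep("HOM_B", 5), rep("HET", n - b - 5)),
                    coords)
  reg3 <- pair_sectors(red3, white2)
  expect_true("4:0B" %in% reg3$label)
  expect_equal(reg3$label[reg3$label != "2:2"], c("4:0B", "3:1B"))

  # partition covers every chromosome exactly once, no gaps or overlaps
  for (reg_i in list(reg, reg2, reg3)) {
    expect_equal(sum(reg_i$n_markers), n)
    expect_equal(reg_i$start_coord[1], coords[1])
    expect_equal(reg_i$end_coord[nrow(reg_i)], coords[n])
  }
  expect_error(pair_sectors(red, toy_calls(rep("HET", 3))), "different marker maps")
})

test_that("tract classification follows the decision table", {
  cases <- list(
    list(c("2:2"), "NONE", "NONE"),
    list(c("2:2", "3:1B", "2:2"), "THREE_ONE", "SCB"),
    list(c("2:2", "4:0B", "2:2"), "FOUR_ZERO", "DSCB"),
    list(c("2:2", "4:0B", "3:1B", "2:2"), "HYBRID", "DSCB"),
    list(c("2:2", "3:1B", "4:0B", "3:1B"), "HYBRID", "DSCB"),
    list(c("3:1B", "2:2", "3:1B"), "COMPLEX", "SCB"),
    list(c("2:2", "3:1B", "3:1A"), "COMPLEX", "UNCLASSIFIED"),
    list(c("4:0B", "2:2", "3:1B"), "COMPLEX", "DSCB"),
    list(c("2:2", "4:0B", "3:1A"), "COMPLEX", "DSCB"),
    list(c("2:2", "4:0A", "4:0B"), "COMPLEX", "DSCB"))
  for (cs in cases) {
    res <- classify_tract(toy_regions(cs[[1]]))
    expect_equal(res$tract_class, cs[[2]], info = paste(cs[[1]], collapse = ","))
    expect_equal(res$origin, cs[[3]], info = paste(cs[[1]], collapse = ","))
  }
  # sub-threshold regions are disregarded
  reg <- toy_regions(c("2:2", "3:1B", "2:2"), n_markers = c(5, 1, 5))
  expect_equal(classify_tract(reg)$tract_class, "NONE")
})

test_that("every tract containing a 4:0 region is labeled DSCB", {
  labs <- c("2:2", "3:1A", "3:1B", "4:0A", "4:0B")
  set.seed(41)
  for (rep in 1:100) {
    seq_labs <- sample(labs, sample(1:5, 1), replace = TRUE)
    res <- classify_tract(toy_regions(seq_labs))
    if (any(seq_labs %in% c("4:0A", "4:0B")))
      expect_equal(res$origin, "DSCB")
  }
})

test_that("tract length averages the converted and flanking spans", {
  map <- toy_map(list(chrV = c(5000, 6000, 10000, 12000, 16000, 17500, 20000)))
  # converted markers 6000..16000 (span 10000); flanks 5000 and 17500 (12500)
  tl <- tract_length("chrV", 6000, 16000, map)
  expect_equal(tl$min_len, 10000)
  expect_equal(tl$max_len, 12500)
  expect_equal(tl$length, 11250)
  expect_false(tl$clipped)

  # single converted marker with flanks 2 kb apart
  map2 <- toy_map(list(chrV = c(9000, 10000, 11000)))
  tl2 <- tract_length("chrV", 10000, 10000, map2)
  expect_equal(tl2$min_len, 0)
  expect_equal(tl2$length, 1000)

  # missing distal flank clips to the chromosome end and flags
  tl3 <- tract_length("chrV", 10000, 11000, map2, chrom_length = 12000)
  expect_true(tl3$clipped)
  expect_equal(tl3$max_len, 12000 - 9000)
  expect_true(tl3$min_len <= tl3$length && tl3$length <= tl3$max_len)
})

test_that("unselected events are classified by position and copy state", {
  coords <- seq(5000, 150000, by = 5000)
  n <- length(coords)
  # terminal LOH run reaching the right end
  st <- rep("HET", n); st[coords >= 120000] <- "HOM_B"
  ev <- classify_unselected_events(toy_calls(st, coords, chrom = "chrII"),
                                   toy_map(list(chrII = coords)))
  expect_equal(ev$type, "BIR_OR_CO_TERMINAL")
  expect_equal(ev$gaining_haplotype, "B")
  expect_equal(ev$hom_boundary, 120000)
  expect_equal(ev$t2_distal, 150000)

  # interstitial run flanked by HET
  st2 <- rep("HET", n); st2[coords >= 40000 & coords <= 55000] <- "HOM_B"
  ev2 <- classify_unselected_events(toy_calls(st2, coords, chrom = "chrII"),
                                    toy_map(list(chrII = coords)))
  expect_equal(ev2$type, "GC_INTERSTITIAL")
  expect_equal(ev2$t1_proximal, 35000)
  expect_equal(ev2$t1_distal, 40000)
  expect_equal(ev2$t2_proximal, 55000)
  expect_equal(ev2$t2_distal, 60000)
  expect_equal(ev2$length, mean(c(55000 - 40000, 60000 - 35000)))

  # chromosome-wide copy gain: trisomy
  ev3 <- classify_unselected_events(
    toy_calls(rep("HET", n), coords, chrom = "chrXII",
              copy_states = rep("DUP", n)),
    toy_map(list(chrXII = coords)))
  expect_equal(ev3$type, "TRISOMY")

  # terminal deletion run
  cp <- rep("NORMAL", n); cp[coords <= 20000] <- "DEL"
  ev4 <- classify_unselected_events(
    toy_calls(rep("HET", n), coords, chrom = "chrI", copy_states = cp),
    toy_map(list(chrI = coords)))
  expect_equal(ev4$type, "TERMINAL_DEL")
})

test_that("selected crossovers are detected and validated on chromosome V", {
  cfg <- small_sim_config(noise_sd = 0, unselected_rate = 0)
  hits <- 0
  for (s in 1:20) {
    sim <- simulate_sectored_colony(cfg, seed = 700 + s)
    red <- resolve_ambiguous(call_genotypes(
      sim$map, normalize_ratios(render_probe_intensities(sim$red, sim$map, cfg, s))))
    white <- resolve_ambiguous(call_genotypes(
      sim$map, normalize_ratios(render_probe_intensities(sim$white, sim$map, cfg, s + 1))))
    det <- detect_selected_crossover(red, white, sim$map,
                                     chrom_length = cfg$chrom_lengths[["chrV"]])
    expect_true(det$selected)
    hits <- hits + det$selected
    truth <- sim$truth[1, ]
    expect_equal(det$event$tract_class, truth$tract_class)
    # origin is recoverable from the visible tract except when a DSCB's 4:0
    # region is too short to span two markers (it then looks like a 3:1)
    if (truth$tract_class %in% c("FOUR_ZERO", "HYBRID") ||
        (truth$tract_class == "THREE_ONE" && truth$origin == "SCB"))
      expect_equal(det$event$origin, truth$origin)
    # red sector fully heterozygous on chrV: selection failure
    if (s == 1) {
      het_red <- red; het_red$state[het_red$chrom == "chrV"] <- "HET"
      fail <- detect_selected_crossover(het_red, white, sim$map)
      expect_false(fail$selected)
    }
  }
  expect_equal(hits, 20)
})

test_that("noise-free transitions recover ground-truth breakpoints to marker resolution", {
  cfg <- small_sim_config(noise_sd = 0, unselected_rate = 0)
  for (s in 1:10) {
    sim <- simulate_sectored_colony(cfg, seed = 800 + s)
    truth <- sim$truth[1, ]
    if (truth$tract_class == "NONE") next
    red <- resolve_ambiguous(call_genotypes(
      sim$map, normalize_ratios(render_probe_intensities(sim$red, sim$map, cfg, s))))
    white <- resolve_ambiguous(call_genotypes(
      sim$map, normalize_ratios(render_probe_intensities(sim$white, sim$map, cfg, s + 1))))
    det <- detect_selected_crossover(red, white, sim$map,
                                     chrom_length = cfg$chrom_lengths[["chrV"]])
    mkV <- sim$map$coord[sim$map$chrom == "chrV"]
    spacing <- max(diff(mkV))
    true_len <- truth$tract_hi - truth$breakpoint
    expect_lt(abs(det$event$length - true_len), 2 * spacing)
  }
})
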