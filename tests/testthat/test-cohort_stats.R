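# Cohort assembly, group comparisons, thickness maps, regional contrasts.

# lightweight synthetic cohort table (no meshes): one property at given
# levels with per-specimen values
fake_table <- function(h_values, o_values, property = "cortical_area",
                       levels = 0.5) {
  rows <- list()
  for (li in seq_along(levels)) {
    for (i in seq_along(h_values)) {
      rows[[length(rows) + 1]] <- data.frame(
        specimen_id = sprintf("H%02d", i), group = "healthy",
        level_index = li, level_fraction = levels[li],
        property_name = property, value = h_values[i])
    }
    for (i in seq_along(o_values)) {
      rows[[length(rows) + 1]] <- data.frame(
        specimen_id = sprintf("O%02d", i), group = "osteoporosis",
        level_index = li, level_fraction = levels[li],
        property_name = property, value = o_values[i])
    }
  }
  do.call(rbind, rows)
}

test_that("build_cohort_table stacks specimens and records failures", {
  sp <- generate_bone(tube_spec(n_rings = 16L, n_angular = 32L))
  cfg <- sampling_config(n_sections = 4)
  d1 <- specimen_properties(sp, cfg)
  d2 <- d1
  d2$specimen_id <- "other"
  d2$group <- "osteoporosis"
  failed <- simpleError("synthetic failure")
  long <- build_cohort_table(list(d1, d2, failed))
  n_props <- length(boneCSG:::section_property_names())
  expect_equal(nrow(long), 2 * 4 * n_props)
  expect_length(attr(long, "failures"), 1L)
  expect_setequal(unique(long$specimen_id), c(d1$specimen_id[1], "other"))

  # determinism
  long2 <- build_cohort_table(list(d1, d2, failed))
  expect_identical(long, long2)

  # mixed sampling configs are rejected
  d3 <- specimen_properties(sp, sampling_config(n_sections = 3))
  d3$specimen_id <- "third"
  expect_error(build_cohort_table(list(d1, d3)), "different sampling")
})

test_that("group_compare reports ratio of means and handles degeneracy", {
  tbl <- fake_table(rep(100, 5), rep(70, 5))
  gc <- group_compare(tbl, "cortical_area", level = 0.5)
  expect_equal(gc$ratio_percent, 70)
  # zero within-group variance with distinct means: perfect separation
  expect_equal(gc$p_value, 0)
  expect_match(gc$test_name, "degenerate")

  tbl2 <- fake_table(c(10, 11, 12, 13), c(10, 11, 12, 13))
  gc2 <- group_compare(tbl2, "cortical_area", level = 0.5,
                       test = "mann_whitney")
  expect_equal(gc2$ratio_percent, 100)
  expect_gt(gc2$p_value, 0.99)

  expect_error(group_compare(tbl, "no_such"), "unknown property")
  expect_error(group_compare(fake_table(100, 70), "cortical_area",
                             level = 0.5), "at least 2")
})

test_that("group_compare recovers a 0.70 ratio with power (Monte Carlo)", {
  set.seed(123)
  n_rep <- 200
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    h <- 100 * exp(rnorm(15, sd = 0.05))
    o <- 70 * exp(rnorm(15, sd = 0.05))
    gc <- group_compare(fake_table(h, o), "cortical_area", level = 0.5)
    ok[r] <- gc$p_value < 0.001 &&
      gc$ratio_percent >= 67 && gc$ratio_percent <= 73
  }
  expect_gte(mean(ok), 0.95)
})

test_that("thickness maps have the right shape, scaling and gradients", {
  cfg <- sampling_config(n_sections = 6)
  sp <- generate_bone(tube_spec(n_rings = 16L, n_angular = 48L))
  m <- thickness_map(sp, config = cfg)
  expect_equal(dim(m$thickness), c(6L, 21L))
  # uniform tube: thickness constant up to contour faceting (chord sagitta
  # ~ R (1 - cos(pi/n_angular)) ~ 0.03 mm here)
  expect_lt(diff(range(m$thickness)), 0.05)

  # exactly constant sections trip the degenerate-normalization guard
  cfg3 <- sampling_config(n_sections = 3, n_semilandmarks = 5)
  ang <- 2 * pi * (0:4) / 5
  sec0 <- structure(list(level = 0.5, z_height = 0,
                         periosteal_slm = cbind(2 * cos(ang), 2 * sin(ang)),
                         endosteal_slm = cbind(cos(ang), sin(ang)),
                         ray_angles = ang),
                    class = "cross_section")
  secs <- replicate(3, sec0, simplify = FALSE)
  fake_spec <- list(specimen_id = "flat", group = "healthy")
  mf <- thickness_map(fake_spec, sections = secs, config = cfg3)
  expect_lt(diff(range(mf$thickness)), 1e-12)
  expect_true(all(mf$scaled == 0.5))

  # linearly tapering cortex: endosteal radius grows with level, so the
  # per-level mean thickness decreases monotonically
  taper <- synthetic_bone_spec(n_rings = 16L, n_angular = 48L,
                               a_p = 15, b_p = 15,
                               a_e = function(t) 8 + 4 * t,
                               b_e = function(t) 8 + 4 * t)
  mt <- thickness_map(generate_bone(taper), config = cfg)
  means <- rowMeans(mt$thickness)
  expect_true(all(diff(means) < 0))
  expect_equal(range(mt$scaled), c(0, 1))
})

test_that("ray sectors partition the rays by anatomical quadrant", {
  ang <- 2 * pi * (0:20) / 21
  sec <- ray_sectors(ang)
  expect_identical(sec[1], "lateral")            # +x
  expect_identical(sec[ang == 2 * pi * 5 / 21], "anterior")
  expect_setequal(unique(sec), c("anterior", "posterior", "medial",
                                 "lateral"))
  expect_equal(sum(table(sec)), 21)
})

test_that("regional contrast localizes thinning to anterior/lateral sectors", {
  cfg <- sampling_config(n_sections = 10)
  base <- tube_spec(R = 15, r = 10, n_rings = 20L, n_angular = 48L)
  co <- generate_cohort(3, 3, variation = 0.02, seed = 4, base_spec = base,
                        osteo_mode = "regional_thinning", thin_depth = 0.6,
                        levels = section_levels(cfg))
  maps <- lapply(co$specimens, thickness_map, config = cfg)
  rc <- regional_contrast(maps, level_band = c(0.20, 0.45))
  expect_setequal(rc$sector, c("anterior", "posterior", "medial",
                               "lateral"))
  d <- setNames(rc$difference_mm, rc$sector)
  expect_gt(d["anterior"], d["posterior"])
  expect_gt(d["anterior"], d["medial"])
  expect_gt(d["lateral"], d["posterior"])
  expect_gt(d["lateral"], d["medial"])

  # isotropic expansion: all four sector differences equal within noise
  co_u <- generate_cohort(3, 3, variation = 0, seed = 4, base_spec = base,
                          ca_ratio = 0.8, levels = section_levels(cfg))
  maps_u <- lapply(co_u$specimens, thickness_map, config = cfg)
  rc_u <- regional_contrast(maps_u, level_band = c(0.20, 0.45))
  # equal up to contour faceting noise (~1e-3 mm at this resolution)
  expect_lt(diff(range(rc_u$difference_mm)), 1e-3)

  # zero-variation identical cohorts -> zero differences
  co_0 <- generate_cohort(2, 2, variation = 0, seed = 1, base_spec = base,
                          f = 1, levels = section_levels(cfg))
  maps_0 <- lapply(co_0$specimens, thickness_map, config = cfg)
  rc_0 <- regional_contrast(maps_0, level_band = c(0.25, 0.45))
  expect_true(all(abs(rc_0$difference_mm) < 1e-9))
})

test_that("summarize_run reports headline comparisons and ratio ranges", {
  tbl <- fake_table(c(100, 101, 99, 100), c(70, 71, 69, 70),
                    levels = c(0.2, 0.4, 0.6, 0.8))
  s <- summarize_run(tbl)
  expect_equal(nrow(s$comparisons), 4L)
  expect_true(all(s$comparisons$significant))
  expect_equal(s$ratio_ranges$ratio_min, 70, tolerance = 1e-6)
  expect_equal(s$ratio_ranges$ratio_max, 70, tolerance = 1e-6)

  # healthy-only input degrades gracefully
  h_only <- tbl[tbl$group == "healthy", ]
  s2 <- summarize_run(h_only)
  expect_null(s2$comparisons)
  expect_match(s2$note, "absent")

  # deterministic
  expect_identical(summarize_run(tbl), s)

  # Benjamini-Hochberg switch only adjusts p-values upward
  s3 <- summarize_run(tbl, p_adjust = "BH")
  expect_true(all(s3$comparisons$p_value >= s$comparisons$p_value))
})
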