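#' Process one specimen into a per-section property table
#'
#' Sections an oriented specimen and computes all section properties at
#' every sampling level.
#'
#' @param spec an oriented `bone_specimen`.
#' @param config a [sampling_config()].
#' @return data.frame with `specimen_id`, `group`, `level_index`,
#'   `level_fraction` and one column per section property.
#' @export
specimen_properties <- function(spec, config = sampling_config()) {
  sections <- section_specimen(spec, config)
  rows <- lapply(seq_along(sections), function(i) {
    p <- section_properties(sections[[i]])
    data.frame(specimen_id = spec$specimen_id, group = spec$group,
               level_index = i, level_fraction = p$level,
               as.data.frame(p[section_property_names()]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble a long-format cohort table
#'
#' Stacks per-specimen property tables (from [specimen_properties()] or the
#' `process` command's CSVs) into long format: one row per
#' (specimen, level, property). Per-specimen processing failures are
#' carried in attribute `"failures"`, never silently dropped.
#'
#' @param property_tables list of per-specimen wide data.frames; entries
#'   inheriting from `try-error` (or `NULL`) are recorded as failures.
#' @return data.frame with columns `specimen_id`, `group`, `level_index`,
#'   `level_fraction`, `property_name`, `value`.
#' @export
build_cohort_table <- function(property_tables) {
  failed <- vapply(property_tables, function(x) {
    is.null(x) || inherits(x, "try-error") || inherits(x, "error")
  }, logical(1))
  failures <- property_tables[failed]
  tables <- property_tables[!failed]
  if (length(tables) == 0L) stop("no successfully processed specimens")
  n_levels <- vapply(tables, nrow, integer(1))
  level_sets <- vapply(tables, function(d) {
    paste(signif(d$level_fraction, 10), collapse = ",")
  }, character(1))
  if (length(unique(n_levels)) != 1L || length(unique(level_sets)) != 1L) {
    stop("specimens were processed with different sampling configurations")
  }
  props <- setdiff(names(tables[[1L]]),
                   c("specimen_id", "group", "level_index", "level_fraction"))
  long <- do.call(rbind, lapply(tables, function(d) {
    data.frame(
      specimen_id = rep(d$specimen_id, times = length(props)),
      group = rep(d$group, times = length(props)),
      level_index = rep(d$level_index, times = length(props)),
      level_fraction = rep(d$level_fraction, times = length(props)),
      property_name = rep(props, each = nrow(d)),
      value = unlist(d[props], use.names = FALSE),
      stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  attr(long, "failures") <- failures
  long
}

#' Two-group comparison of one property at one level
#'
#' Compares per-specimen values between the healthy and osteoporosis groups
#' with Welch's two-sample t-test (default) or the Mann-Whitney U test
#' (normal approximation with mid-rank tie handling), and reports the
#' ratio of group means as a percentage
#' (`100 * mean(osteo) / mean(healthy)`).
#'
#' @param table long cohort table from [build_cohort_table()].
#' @param property property name.
#' @param level level fraction (matched to the nearest sampled level) or
#'   level index via `level_index`.
#' @param level_index optional explicit level index.
#' @param test `"welch"` or `"mann_whitney"`.
#' @param alpha significance threshold (default 0.05).
#' @return one-row data.frame (`group_comparison`): property, level, group
#'   means, `ratio_percent`, test name, statistic, p-value, significance.
#' @export
group_compare <- function(table, property, level = NULL, level_index = NULL,
                          test = c("welch", "mann_whitney"), alpha = 0.05) {
  test <- match.arg(test)
  sub <- table[table$property_name == property, , drop = FALSE]
  if (nrow(sub) == 0L) stop("unknown property: ", property)
  if (is.null(level_index)) {
    if (is.null(level)) stop("give either level or level_index")
    lf <- sort(unique(sub$level_fraction))
    nearest <- lf[which.min(abs(lf - level))]
    sub <- sub[abs(sub$level_fraction - nearest) < 1e-12, , drop = FALSE]
  } else {
    sub <- sub[sub$level_index == level_index, , drop = FALSE]
  }
  h <- sub$value[sub$group == "healthy"]
  o <- sub$value[sub$group == "osteoporosis"]
  if (length(h) < 2L || length(o) < 2L) {
    stop("need at least 2 specimens per group at this level")
  }
  if (stats::var(h) + stats::var(o) < 1e-30) {
    # both groups constant: the test is undefined; perfect separation when
    # the means differ, a perfect null when they coincide
    statistic <- NA_real_
    p_value <- if (isTRUE(all.equal(mean(h), mean(o)))) 1 else 0
    test_name <- paste0(test, " (degenerate: zero within-group variance)")
  } else if (test == "welch") {
    tt <- stats::t.test(h, o, var.equal = FALSE)
    statistic <- unname(tt$statistic)
    p_value <- tt$p.value
    test_name <- "welch_t"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(h, o, exact = FALSE,
                                              correct = TRUE))
    statistic <- unname(wt$statistic)
    p_value <- if (is.nan(wt$p.value)) 1 else wt$p.value
    test_name <- "mann_whitney"
  }
  structure(data.frame(
    property_name = property,
    level_fraction = sub$level_fraction[1L],
    mean_healthy = mean(h), mean_osteo = mean(o),
    ratio_percent = 100 * mean(o) / mean(h),
    test_name = test_name, statistic = statistic, p_value = p_value,
    significant = is.finite(p_value) && p_value < alpha,
    stringsAsFactors = FALSE), class = c("group_comparison", "data.frame"))
}

#' Per-specimen radial thickness map
#'
#' Assembles the `n_sections x n_semilandmarks` matrix of radial cortical
#' thickness (rows ordered distal to proximal, columns by ray index) plus a
#' per-specimen min-max scaled variant in [0, 1]. For the scaled heat-map
#' convention, high thickness maps to 1 (rendered blue) and low thickness
#' to 0 (rendered red); a constant matrix scales to 0.5 everywhere.
#'
#' @param spec an oriented `bone_specimen`.
#' @param sections list of sampled sections from [section_specimen()]; if
#'   `NULL` they are computed.
#' @param config a [sampling_config()].
#' @return list of class `thickness_map` with `specimen_id`, `group`,
#'   `thickness` (matrix), `scaled` (matrix), `levels`, `ray_angles`,
#'   `color_scale`.
#' @export
thickness_map <- function(spec, sections = NULL,
                          config = sampling_config()) {
  if (is.null(sections)) sections <- section_specimen(spec, config)
  mat <- t(vapply(sections, radial_thickness,
                  numeric(config$n_semilandmarks)))
  rng <- range(mat)
  scaled <- if (diff(rng) < 1e-12) {
    matrix(0.5, nrow(mat), ncol(mat))
  } else {
    (mat - rng[1L]) / diff(rng)
  }
  structure(list(specimen_id = spec$specimen_id, group = spec$group,
                 thickness = mat, scaled = scaled,
                 levels = vapply(sections, `[[`, numeric(1), "level"),
                 ray_angles = sections[[1L]]$ray_angles,
                 color_scale = "high=1 (blue) ... low=0 (red)"),
            class = "thickness_map")
}

#' Anatomical quadrant of each semilandmark ray
#'
#' Left-femur convention with +x lateral and +y anterior: rays within 45
#' degrees of +x are `lateral`, of +y `anterior`, of -x `medial`, of -y
#' `posterior`.
#'
#' @param angles ray angles in radians.
#' @return character vector of sector labels.
#' @export
ray_sectors <- function(angles) {
  a <- atan2(sin(angles), cos(angles))  # wrap to (-pi, pi]
  sector <- character(length(a))
  sector[abs(a) <= pi / 4] <- "lateral"
  sector[a > pi / 4 & a <= 3 * pi / 4] <- "anterior"
  sector[abs(a) > 3 * pi / 4] <- "medial"
  sector[a < -pi / 4 & a >= -3 * pi / 4] <- "posterior"
  sector
}

#' Regional thickness contrast between groups
#'
#' For each anatomical quadrant (anterior, posterior, medial, lateral),
#' averages each specimen's radial thickness over the rays of that sector
#' and the levels of a band, then reports the healthy-minus-osteoporosis
#' mean difference with a per-sector two-sample test.
#'
#' @param maps list of [thickness_map()] objects covering both groups.
#' @param level_band `c(lo, hi)` band of level fractions (default the
#'   distal-diaphysis band `c(0.20, 0.45)`).
#' @param test `"welch"` or `"mann_whitney"`.
#' @param alpha significance threshold.
#' @return data.frame with one row per sector: means, `difference_mm`,
#'   statistic, p-value, significance.
#' @export
regional_contrast <- function(maps, level_band = c(0.20, 0.45),
                              test = c("welch", "mann_whitney"),
                              alpha = 0.05) {
  test <- match.arg(test)
  sectors <- c("anterior", "posterior", "medial", "lateral")
  lev <- maps[[1L]]$levels
  in_band <- lev >= level_band[1L] & lev <= level_band[2L]
  if (!any(in_band)) stop("level band contains no sampled levels")
  ray_sec <- ray_sectors(maps[[1L]]$ray_angles)
  groups <- vapply(maps, `[[`, character(1), "group")
  rows <- lapply(sectors, function(s) {
    cols <- ray_sec == s
    if (!any(cols)) stop("empty sector: ", s)
    per_spec <- vapply(maps, function(m) {
      mean(m$thickness[in_band, cols, drop = FALSE])
    }, numeric(1))
    h <- per_spec[groups == "healthy"]
    o <- per_spec[groups == "osteoporosis"]
    if (length(h) < 2L || length(o) < 2L) {
      stop("need at least 2 specimens per group")
    }
    if (stats::var(h) + stats::var(o) < 1e-30) {
      stat <- NA_real_
      p <- if (isTRUE(all.equal(mean(h), mean(o)))) 1 else 0
    } else if (test == "welch") {
      tt <- stats::t.test(h, o, var.equal = FALSE)
      stat <- unname(tt$statistic); p <- tt$p.value
    } else {
      wt <- suppressWarnings(stats::wilcox.test(h, o, exact = FALSE))
      stat <- unname(wt$statistic)
      p <- if (is.nan(wt$p.value)) 1 else wt$p.value
    }
    data.frame(sector = s, mean_healthy = mean(h), mean_osteo = mean(o),
               difference_mm = mean(h) - mean(o), statistic = stat,
               p_value = p, significant = is.finite(p) && p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize a cohort run at the headline levels
#'
#' Computes group comparisons for every property at the four headline
#' sampling locations (80, 60, 40, 20 percent biomechanical length, mapped
#' to the nearest sampled levels) plus the min/max ratio-of-means across
#' those levels per property -- the "X--Y percent of healthy" style range.
#' With fewer than two specimens in either group, comparisons are marked
#' absent rather than failing.
#'
#' @param table long cohort table.
#' @param headline_levels level fractions to report (default
#'   `c(0.80, 0.60, 0.40, 0.20)`).
#' @param test,alpha passed to [group_compare()].
#' @param p_adjust optional p-value adjustment method (e.g. `"BH"`);
#'   `"none"` (default) reports per-location significance unadjusted.
#' @return list with `comparisons` (data.frame) and `ratio_ranges`
#'   (data.frame of min/max ratio per property), or a degraded report when
#'   a group is missing.
#' @export
summarize_run <- function(table, headline_levels = c(0.80, 0.60, 0.40, 0.20),
                          test = "welch", alpha = 0.05, p_adjust = "none") {
  props <- unique(table$property_name)
  n_h <- length(unique(table$specimen_id[table$group == "healthy"]))
  n_o <- length(unique(table$specimen_id[table$group == "osteoporosis"]))
  if (n_h < 2L || n_o < 2L) {
    return(list(comparisons = NULL, ratio_ranges = NULL,
                note = sprintf(
                  "comparisons absent: need >= 2 specimens per group (healthy %d, osteoporosis %d)",
                  n_h, n_o)))
  }
  grid <- expand.grid(property = props, level = headline_levels,
                      stringsAsFactors = FALSE)
  comps <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    group_compare(table, grid$property[i], level = grid$level[i],
                  test = test, alpha = alpha)
  }))
  if (p_adjust != "none") {
    comps$p_value <- stats::p.adjust(comps$p_value, method = p_adjust)
    comps$significant <- comps$p_value < alpha
  }
  ranges <- do.call(rbind, lapply(split(comps, comps$property_name),
                                  function(d) {
    data.frame(property_name = d$property_name[1L],
               ratio_min = min(d$ratio_percent),
               ratio_max = max(d$ratio_percent),
               stringsAsFactors = FALSE)
  }))
  rownames(ranges) <- NULL
  list(comparisons = comps, ratio_ranges = ranges)
}
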