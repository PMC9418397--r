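# Synthetic plantar thermogram phantoms.
#
# The generator exists so that every downstream stage (segmentation,
# angiosome partition, TCI labeling, balancing, CNN training, evaluation) is
# testable without the clinical dataset. It is a deliberately simple stated
# world: a foot-shaped footprint on an ambient background, a symmetric
# "butterfly" arch elevation for controls, and per-angiosome warming plus
# hotspots and a medio-lateral tilt for diabetic grades, with the per-region
# mean temperatures corrected so the analytic TCI of the noise-free field
# equals the requested target exactly.

#' Phantom generation settings
#'
#' @param target_grade intended severity class 0..5 (0 = control).
#' @param target_tci requested TCI in degrees Celsius. Must lie inside the
#'   grade's bin; default is the bin midpoint (class 5 uses 6, its sampling
#'   bin being capped at 7). Ignored for grade 0, whose symmetric
#'   construction yields a TCI of 0.1.
#' @param shape image dimensions, default `c(180, 80)` (rows x cols).
#' @param background_temp ambient background temperature, degrees Celsius.
#' @param arch_elevation amplitude of the arch ("butterfly") elevation,
#'   degrees Celsius; attenuated with increasing grade.
#' @param hotspot_count number of focal warm lesions; default equals the
#'   grade.
#' @param hotspot_amplitude peak lesion amplitude, degrees Celsius.
#' @param noise_sd additive Gaussian pixel noise, degrees Celsius.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param side `"right"`, `"left"`, or `NULL` to draw at random.
#' @param region_means optional named vector (MPA, LPA, MCA, LCA) of exact
#'   target regional mean temperatures, overriding the TCI-driven offsets
#'   (used to build feet with prescribed regional means).
#' @param fractions angiosome geometry, see [partition_angiosomes()].
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(target_grade = 0, target_tci = NULL,
                           shape = c(180, 80), background_temp = 20,
                           arch_elevation = 1.5, hotspot_count = NULL,
                           hotspot_amplitude = 2, noise_sd = 0.2,
                           seed = NULL, side = NULL, region_means = NULL,
                           fractions = c(calcaneal = 0.27, medial = 0.5)) {
  stopifnot(target_grade %in% 0:5, noise_sd >= 0,
            length(shape) == 2, shape[1] >= 8, shape[2] >= 8)
  bins <- severity_bins()
  if (is.null(target_tci) && target_grade > 0 && is.null(region_means))
    target_tci <- mean(bins[[target_grade]])
  if (!is.null(target_tci) && target_grade > 0) {
    b <- bins[[target_grade]]
    if (!(target_tci > b[1] && target_tci <= b[2]))
      stop(sprintf("target_tci %.3f outside grade %d bin (%g, %g]",
                   target_tci, target_grade, b[1], b[2]))
  }
  if (is.null(hotspot_count)) hotspot_count <- target_grade
  structure(list(target_grade = as.integer(target_grade),
                 target_tci = target_tci, shape = as.integer(shape),
                 background_temp = background_temp,
                 arch_elevation = arch_elevation,
                 hotspot_count = as.integer(hotspot_count),
                 hotspot_amplitude = hotspot_amplitude, noise_sd = noise_sd,
                 seed = seed, side = side, region_means = region_means,
                 fractions = fractions),
            class = "phantom_config")
}

# TCI sampling bins per diabetic grade; grade 5's open bin is capped at 7.
#' @noRd
severity_bins <- function(cap = 7) {
  list(`1` = c(0, 2), `2` = c(2, 3), `3` = c(3, 4), `4` = c(4, 5),
       `5` = c(5, cap))
}

# Foot-shaped footprint (right foot, toes at row 1), horizontally symmetric.
# Even widths per row so the default medial fraction of 0.5 splits each row
# into exact mirror halves.
#' @noRd
foot_footprint <- function(H, W) {
  r0 <- max(2L, round(0.04 * H)); r1 <- H - r0 + 1L
  L <- r1 - r0 + 1L
  u <- seq(0, 1, length.out = L)
  ctrl_t <- c(0, 0.06, 0.18, 0.35, 0.50, 0.62, 0.78, 0.92, 1)
  ctrl_v <- c(0.30, 0.74, 0.95, 0.88, 0.72, 0.62, 0.76, 0.70, 0.28)
  prof <- clamp(stats::spline(ctrl_t, ctrl_v, xout = u)$y, 0.15, 1)
  hw <- pmin(pmax(round(prof * 0.46 * W), 1L), (W - 2L) %/% 2L)
  mask <- matrix(FALSE, H, W)
  cx <- (W + 1) / 2
  cols <- seq_len(W)
  for (i in seq_len(L)) {
    mask[r0 + i - 1L, abs(cols - cx) <= hw[i] - 0.5 + 1e-9] <- TRUE
  }
  mask
}

#' Generate one synthetic plantar thermogram
#'
#' Builds the phantom described by `cfg` and returns both the thermogram and
#' its ground truth (footprint, per-region means of the noise-free field,
#' analytic TCI, intended class). With `noise_sd = 0` the labeling pipeline
#' recovers the target TCI to within 1e-6 degrees Celsius.
#'
#' @param cfg a [phantom_config()].
#' @param subject_id identifier stored in the thermogram.
#' @return list with elements `thermogram` and `truth`.
#' @export
generate_phantom <- function(cfg = phantom_config(), subject_id = "phantom") {
  stopifnot(inherits(cfg, "phantom_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  H <- cfg$shape[1]; W <- cfg$shape[2]
  g <- cfg$target_grade
  refs <- reference_temperatures()
  mask <- foot_footprint(H, W)
  part <- partition_angiosomes(mask, side = "right", fractions = cfg$fractions)
  lab <- part$labels

  side <- cfg$side
  if (is.null(side)) side <- sample(c("right", "left"), 1)

  # target regional means
  joint_zone_targets <- FALSE
  if (!is.null(cfg$region_means)) {
    target <- cfg$region_means[ANGIOSOMES]
    if (any(is.na(target))) stop("region_means must name MPA, LPA, MCA, LCA")
  } else if (g == 0) {
    # symmetric control: medial/lateral share the zone-average reference so
    # the noise-free field is an exact mirror image of itself
    target <- c(MPA = mean(refs[c("MPA", "LPA")]),
                LPA = mean(refs[c("MPA", "LPA")]),
                MCA = mean(refs[c("MCA", "LCA")]),
                LCA = mean(refs[c("MCA", "LCA")]))
    joint_zone_targets <- TRUE
  } else {
    u <- stats::runif(4, 0.6, 1.4)
    offsets <- cfg$target_tci * 4 * u / sum(u)  # mean(|offsets|) == target_tci
    target <- refs + offsets
  }

  temps <- matrix(cfg$background_temp, H, W)
  for (i in 1:4) temps[lab == i] <- target[i]

  # arch elevation ("butterfly"), symmetric about the foot axis
  rr <- range(which(rowSums(mask) > 0))
  L <- rr[2] - rr[1] + 1
  cx <- (W + 1) / 2
  rowm <- matrix(seq_len(H), H, W)
  colm <- matrix(seq_len(W), H, W, byrow = TRUE)
  arch_amp <- cfg$arch_elevation * if (g == 0) 1 else max(0.2, 1 - g / 6)
  bump <- arch_amp * exp(-(((rowm - (rr[1] + 0.45 * L))^2) / (2 * (0.16 * L)^2) +
                             ((colm - cx)^2) / (2 * (0.30 * W)^2)))
  temps[mask] <- temps[mask] + bump[mask]

  # graded disruption: medio-lateral tilt + focal hotspots (diabetic only)
  if (g >= 1 || !is.null(cfg$region_means)) {
    tilt_g <- if (g >= 1) g else 1
    temps[mask] <- temps[mask] + (0.12 * tilt_g * (colm - cx) / (0.5 * W))[mask]
    if (cfg$hotspot_count > 0) {
      idx <- which(mask)
      centers <- sample(idx, cfg$hotspot_count, replace = TRUE)
      for (ci in centers) {
        cr <- ((ci - 1) %% H) + 1; cc <- ((ci - 1) %/% H) + 1
        s <- stats::runif(1, 1.5, 4)
        a <- cfg$hotspot_amplitude * stats::runif(1, 0.5, 1)
        blob <- a * exp(-((rowm - cr)^2 + (colm - cc)^2) / (2 * s^2))
        temps[mask] <- temps[mask] + blob[mask]
      }
    }
  }

  # exact mean correction: per region (or jointly per zone for the symmetric
  # control, preserving mirror symmetry)
  if (joint_zone_targets) {
    plantar <- lab == 1 | lab == 2
    calcan <- lab == 3 | lab == 4
    temps[plantar] <- temps[plantar] + (target["MPA"] - mean(temps[plantar]))
    temps[calcan] <- temps[calcan] + (target["MCA"] - mean(temps[calcan]))
  } else {
    for (i in 1:4) {
      reg <- lab == i
      temps[reg] <- temps[reg] + (target[i] - mean(temps[reg]))
    }
  }

  if (any(temps[mask] < 15 | temps[mask] > 45))
    stop("generation error: non-physical temperatures outside 15-45 degC")

  means_exact <- vapply(1:4, function(i) mean(temps[lab == i]), numeric(1))
  names(means_exact) <- ANGIOSOMES
  tci_exact <- compute_tci(means_exact)
  group <- if (g == 0 && is.null(cfg$region_means)) "control" else "diabetic"
  class_true <- assign_severity_class(tci_exact, group)
  if (g > 0 && is.null(cfg$region_means) && class_true != g)
    stop("internal error: constructed TCI fell outside the requested grade")

  if (cfg$noise_sd > 0)
    temps <- temps + matrix(stats::rnorm(H * W, 0, cfg$noise_sd), H, W)

  if (side == "left") {
    temps <- temps[, W:1, drop = FALSE]
    mask <- mask[, W:1, drop = FALSE]
  }

  list(thermogram = thermogram(temps, subject_id = subject_id, side = side,
                               group = group),
       truth = list(footprint = mask, region_means = means_exact,
                    tci = tci_exact, class = class_true,
                    target_tci = cfg$target_tci, grade = g))
}

#' Generate a labeled synthetic cohort
#'
#' Draws `class_counts[k]` phantoms per class, sampling each diabetic
#' phantom's target TCI uniformly inside its class bin (class 5 in (5, 7]).
#' The default counts are a skewed distribution (controls and mild grades
#' dominate) chosen as an arbitrary emulation of a clinically imbalanced
#' cohort; they are not published values.
#'
#' @param class_counts named integer vector over classes `"0"`..`"5"`.
#' @param noise_sd pixel noise, degrees Celsius.
#' @param shape image dimensions.
#' @param seed master seed; every phantom receives a derived sub-seed.
#' @param dir optional output directory: per-foot CSV matrices plus
#'   `manifest.csv` and `provenance.json` are written there.
#' @param ... further arguments passed to [phantom_config()]
#'   (e.g. `arch_elevation`, `hotspot_amplitude`).
#' @return object of class `labeled_cohort`: list with `thermograms`,
#'   `labels`, `tci`, `truths`, `manifest`, `seed`.
#' @export
generate_cohort <- function(class_counts = c(`0` = 90, `1` = 110, `2` = 50,
                                             `3` = 30, `4` = 18, `5` = 36),
                            noise_sd = 0.2, shape = c(180, 80), seed = 1,
                            dir = NULL, ...) {
  counts <- as.integer(class_counts)
  names(counts) <- names(class_counts)
  if (is.null(names(counts)) || !all(names(counts) %in% as.character(0:5)))
    stop("class_counts must be named with classes 0..5")
  if (any(counts < 0)) stop("class counts must be non-negative")
  n_total <- sum(counts)
  if (n_total == 0) stop("all class counts are zero")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  bins <- severity_bins()
  classes <- rep(as.integer(names(counts)), counts)
  # draw per-phantom targets before generation so the master seed fully
  # determines them
  targets <- vapply(classes, function(k) {
    if (k == 0) NA_real_ else stats::runif(1, bins[[k]][1], bins[[k]][2])
  }, numeric(1))
  thermos <- vector("list", n_total)
  truths <- vector("list", n_total)
  tci <- numeric(n_total)
  rows <- vector("list", n_total)
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_total)) {
    sid <- sprintf("SYN%04d", i)
    cfg <- phantom_config(target_grade = classes[i],
                          target_tci = if (classes[i] == 0) NULL else targets[i],
                          shape = shape, noise_sd = noise_sd,
                          seed = sub_seeds[i], ...)
    ph <- generate_phantom(cfg, subject_id = sid)
    thermos[[i]] <- ph$thermogram
    truths[[i]] <- ph$truth
    tci[i] <- ph$truth$tci
    path <- NA_character_
    if (!is.null(dir)) {
      path <- file.path(dir, paste0(sid, ".csv"))
      write_temperature_matrix(ph$thermogram, path)
    }
    rows[[i]] <- data.frame(subject_id = sid, side = ph$thermogram$side,
                            group = ph$thermogram$group, class = classes[i],
                            tci_truth = tci[i], path = path,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  cohort <- structure(list(thermograms = thermos, labels = classes, tci = tci,
                           truths = truths, manifest = manifest, seed = seed),
                      class = "labeled_cohort")
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(seed = seed, class_counts = as.list(counts),
                              noise_sd = noise_sd, shape = shape),
                         file.path(dir, "provenance.json"), auto_unbox = TRUE)
  }
  cohort
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf("<labeled_cohort> %d thermograms, seed %s\n",
              length(x$thermograms), format(x$seed)))
  print(table(class = x$labels))
  invisible(x)
}

#' Subset a labeled cohort
#'
#' @param cohort a `labeled_cohort`.
#' @param idx integer or logical index into the cohort.
#' @return the subset, a `labeled_cohort`.
#' @export
subset_cohort <- function(cohort, idx) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  structure(list(thermograms = cohort$thermograms[idx],
                 labels = cohort$labels[idx], tci = cohort$tci[idx],
                 truths = cohort$truths[idx],
                 manifest = cohort$manifest[idx, , drop = FALSE],
                 seed = cohort$seed),
            class = "labeled_cohort")
}
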