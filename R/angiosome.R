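# Angiosome partition, regional means, Thermal Change Index (TCI) and the
# six-way severity label.
#
# The plantar foot is divided into four arterial territories (angiosomes):
# medial plantar (MPA), lateral plantar (LPA), medial calcaneal (MCA) and
# lateral calcaneal (LCA). The TCI of a foot is the mean absolute difference
# between its four regional mean temperatures and control-group reference
# values, and drives the severity grading.

ANGIOSOMES <- c("MPA", "LPA", "MCA", "LCA")

#' Control-group reference temperatures per angiosome
#'
#' Mean regional temperatures of the non-diabetic control group used as the
#' reference in the TCI: MPA 25.8, LPA 25.7, MCA 26.4, LCA 26.1 degrees
#' Celsius.
#'
#' @return named numeric vector over `MPA, LPA, MCA, LCA`.
#' @export
reference_temperatures <- function() {
  c(MPA = 25.8, LPA = 25.7, MCA = 26.4, LCA = 26.1)
}

#' Partition a foot mask into the four plantar angiosomes
#'
#' Geometry is defined on the foot's bounding box within the mask: the
#' posterior `calcaneal` fraction of the foot's length forms the calcaneal
#' (heel) zone, the rest the plantar zone. Each zone is split at the
#' `medial` fraction of the foot's width into a medial and a lateral part:
#' MPA/LPA anterior, MCA/LCA posterior. Which image side is medial follows
#' `side` (column 1 is medial for a right foot, lateral for a left foot).
#'
#' @param mask logical foot mask (row 1 = toes).
#' @param side `"right"` or `"left"`.
#' @param fractions named numeric, `c(calcaneal = , medial = )`, both in
#'   (0, 1). Defaults: calcaneal 0.27, medial 0.5.
#' @return object of class `angiosome_partition`: list with `labels`
#'   (integer matrix, 0 = background, 1..4 = MPA, LPA, MCA, LCA),
#'   `fractions`, `side`, `bbox`.
#' @examples
#' mask <- matrix(TRUE, 100, 40)
#' p <- partition_angiosomes(mask, side = "right")
#' table(factor(p$labels, 0:4, c("bg", "MPA", "LPA", "MCA", "LCA")))
#' @export
partition_angiosomes <- function(mask, side = c("right", "left"),
                                 fractions = c(calcaneal = 0.27, medial = 0.5)) {
  side <- match.arg(side)
  if (!is.matrix(mask) || !is.logical(mask)) stop("`mask` must be a logical matrix")
  if (!any(mask)) stop("cannot partition an empty mask")
  fc <- fractions[["calcaneal"]]; fm <- fractions[["medial"]]
  if (!(fc > 0 && fc < 1 && fm > 0 && fm < 1))
    stop("fractions must lie in (0, 1)")
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  L <- rr[2] - rr[1] + 1
  Wd <- cc[2] - cc[1] + 1
  if (L < 2 || Wd < 2) stop("foot bounding box too small to partition")
  n_cal <- min(max(round(fc * L), 1L), L - 1L)
  n_med <- min(max(round(fm * Wd), 1L), Wd - 1L)
  post_rows <- (rr[2] - n_cal + 1):rr[2]
  medial_cols <- if (side == "right") cc[1]:(cc[1] + n_med - 1)
                 else (cc[2] - n_med + 1):cc[2]
  posterior <- matrix(FALSE, nrow(mask), ncol(mask)); posterior[post_rows, ] <- TRUE
  medial <- matrix(FALSE, nrow(mask), ncol(mask)); medial[, medial_cols] <- TRUE
  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[mask & !posterior & medial]  <- 1L  # MPA
  labels[mask & !posterior & !medial] <- 2L  # LPA
  labels[mask & posterior & medial]   <- 3L  # MCA
  labels[mask & posterior & !medial]  <- 4L  # LCA
  for (i in 1:4) {
    if (!any(labels == i))
      stop(sprintf("angiosome partition failed: region %s is empty", ANGIOSOMES[i]))
  }
  structure(list(labels = labels, fractions = c(calcaneal = fc, medial = fm),
                 side = side, bbox = c(rows = rr, cols = cc)),
            class = "angiosome_partition")
}

#' Regional mean temperatures over the four angiosomes
#'
#' @param t a [thermogram()] (or numeric matrix).
#' @param p an [partition_angiosomes()] result with matching shape.
#' @return named numeric vector of mean temperatures (degrees Celsius) over
#'   `MPA, LPA, MCA, LCA`.
#' @export
regional_mean_temperatures <- function(t, p) {
  m <- if (inherits(t, "thermogram")) t$temperatures else t
  if (!identical(dim(m), dim(p$labels)))
    stop("partition shape does not match thermogram shape")
  means <- vapply(1:4, function(i) mean(m[p$labels == i]), numeric(1))
  names(means) <- ANGIOSOMES
  means
}

#' Thermal Change Index (TCI)
#'
#' The TCI of a foot is the mean of the four absolute differences between its
#' angiosome mean temperatures and the control-group references:
#' `TCI = sum(|CG_ang - DM_ang|) / 4` over `ang` in (MPA, LPA, MCA, LCA).
#'
#' @param means named (or MPA-LPA-MCA-LCA ordered) numeric vector of the
#'   foot's four regional mean temperatures, degrees Celsius.
#' @param refs reference temperatures, default [reference_temperatures()].
#' @return the TCI, a non-negative scalar in degrees Celsius.
#' @examples
#' compute_tci(c(MPA = 28.3, LPA = 27.2, MCA = 29.4, LCA = 28.6))  # 2.375
#' @export
compute_tci <- function(means, refs = reference_temperatures()) {
  if (length(means) != 4 || !all(is.finite(means)))
    stop("`means` must be four finite regional temperatures")
  if (!is.null(names(means))) {
    if (!setequal(names(means), ANGIOSOMES))
      stop("`means` names must be MPA, LPA, MCA, LCA")
    means <- means[ANGIOSOMES]
  }
  refs <- refs[ANGIOSOMES]
  mean(abs(refs - means))
}

#' Assign the six-way severity class
#'
#' Control-group feet are class 0 by definition (their TCI is still reported
#' for diagnostics). Diabetic feet are graded from the TCI with
#' upper-inclusive bins: class 1 if `TCI <= 2`; class 2 if `2 < TCI <= 3`;
#' class 3 if `3 < TCI <= 4`; class 4 if `4 < TCI <= 5`; class 5 if
#' `TCI > 5`.
#'
#' @param tci non-negative TCI value, degrees Celsius.
#' @param group `"control"` or `"diabetic"`.
#' @return integer class in 0..5.
#' @export
assign_severity_class <- function(tci, group = c("diabetic", "control")) {
  group <- match.arg(group)
  if (!is.finite(tci) || tci < 0) stop("TCI must be finite and non-negative")
  if (group == "control") return(0L)
  as.integer(findInterval(tci, c(2, 3, 4, 5), left.open = TRUE) + 1L)
}

#' Label a single thermogram (segment, partition, TCI, class)
#'
#' Runs the full per-foot labeling pipeline: foot segmentation, angiosome
#' partition, regional means, TCI, severity class.
#'
#' @param t a [thermogram()].
#' @param ambient_ceiling segmentation threshold, degrees Celsius.
#' @param fractions angiosome geometry, see [partition_angiosomes()].
#' @param refs reference temperatures.
#' @return object of class `tci_result`: list with `regional_means`,
#'   `references`, `tci`, `severity_class`, `subject_id`, `side`, `group`.
#' @export
label_thermogram <- function(t, ambient_ceiling = 22,
                             fractions = c(calcaneal = 0.27, medial = 0.5),
                             refs = reference_temperatures()) {
  stopifnot(inherits(t, "thermogram"))
  mask <- segment_foot(t, ambient_ceiling)
  p <- partition_angiosomes(mask, side = t$side, fractions = fractions)
  means <- regional_mean_temperatures(t, p)
  tci <- compute_tci(means, refs)
  structure(list(regional_means = means, references = refs, tci = tci,
                 severity_class = assign_severity_class(tci, t$group),
                 subject_id = t$subject_id, side = t$side, group = t$group),
            class = "tci_result")
}

#' @export
print.tci_result <- function(x, ...) {
  cat(sprintf("<tci_result> %s (%s, %s): TCI %.3f degC -> class %d\n",
              x$subject_id, x$side, x$group, x$tci, x$severity_class))
  cat("  regional means:",
      paste(sprintf("%s=%.2f", names(x$regional_means), x$regional_means),
            collapse = ", "), "\n")
  invisible(x)
}
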