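# Class-imbalance handling: inverse-frequency class weights, offline
# per-class augmentation to a common target count, and online per-batch
# augmentation.

#' Augmentation policy
#'
#' Offline (dataset-enlarging) operations act on raw temperature matrices:
#' rotation, zoom, horizontal/vertical flip, shear and zoom-in cropping.
#' Online (per-batch) operations act on encoded intensities: brightness and
#' contrast jitter, quality degradation (Gaussian blur) and small affine
#' perturbations. All ranges are symmetric unless a length-2 `c(lo, hi)` is
#' given. Zero-width ranges yield the identity transform.
#'
#' @param rotation offline rotation range, degrees (scalar = plus/minus).
#' @param zoom offline zoom range, `c(lo, hi)`.
#' @param hflip,vflip allow horizontal / vertical flips offline.
#' @param shear offline shear range, degrees.
#' @param crop offline crop fraction in (0.5, 1]; the retained central
#'   fraction, randomly offset, rescaled to the full frame.
#' @param brightness online additive intensity jitter (scalar = plus/minus,
#'   or `c(lo, hi)`).
#' @param contrast online contrast jitter about mid-gray (scalar or range of
#'   the multiplicative deviation).
#' @param blur_sigma maximal online Gaussian blur sigma, pixels.
#' @param online_rotation,online_zoom small online affine ranges.
#' @param seed default seed used by [offline_balance()].
#' @return an `augmentation_policy` list.
#' @export
augmentation_policy <- function(rotation = 15, zoom = c(0.9, 1.1),
                                hflip = TRUE, vflip = FALSE, shear = 10,
                                crop = 0.9, brightness = 0.1, contrast = 0.1,
                                blur_sigma = 0.8, online_rotation = 5,
                                online_zoom = c(0.95, 1.05), seed = 1) {
  as_range <- function(x, center = 0) {
    if (length(x) == 1) c(center - x, center + x) else sort(x)
  }
  stopifnot(crop > 0.5, crop <= 1)
  structure(list(rotation = as_range(rotation), zoom = sort(zoom),
                 hflip = isTRUE(hflip), vflip = isTRUE(vflip),
                 shear = as_range(shear), crop = crop,
                 brightness = as_range(brightness),
                 contrast = as_range(contrast, center = 1),
                 blur_sigma = blur_sigma,
                 online_rotation = as_range(online_rotation),
                 online_zoom = sort(online_zoom), seed = seed),
            class = "augmentation_policy")
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (K * n_c)` with `N` the total sample count and `K` the number
#' of classes, so that `sum(w_c * n_c) = N` (the sample-weighted average
#' weight is 1).
#'
#' @param counts per-class sample counts, all positive.
#' @return numeric vector of weights (names preserved).
#' @examples
#' inverse_frequency_weights(c(10, 40))  # 2.5, 0.625
#' @export
inverse_frequency_weights <- function(counts) {
  if (any(counts <= 0))
    stop("all class counts must be positive (a class is absent from training)")
  sum(counts) / (length(counts) * counts)
}

# Draw one offline geometric transform from the policy. Returns the
# parameters plus a human-readable descriptor for provenance.
#' @noRd
draw_offline_transform <- function(policy, frame_dim) {
  rot <- stats::runif(1, policy$rotation[1], policy$rotation[2])
  zoom <- stats::runif(1, policy$zoom[1], policy$zoom[2])
  shear <- stats::runif(1, policy$shear[1], policy$shear[2])
  hflip <- policy$hflip && stats::runif(1) < 0.5
  vflip <- policy$vflip && stats::runif(1) < 0.5
  crop <- policy$crop
  margin <- (1 - crop) / 2
  dx <- stats::runif(1, -margin, margin) * frame_dim[2]
  dy <- stats::runif(1, -margin, margin) * frame_dim[1]
  list(rot = rot, zoom = zoom, shear = shear, hflip = hflip, vflip = vflip,
       crop = crop, dx = dx, dy = dy,
       descriptor = sprintf(
         "rot=%.2f;zoom=%.3f;shear=%.2f;hflip=%d;vflip=%d;crop=%.2f;dx=%.1f;dy=%.1f",
         rot, zoom, shear, hflip, vflip, crop, dx, dy))
}

#' @noRd
apply_offline_transform <- function(mat, tr, fill) {
  warp_affine(mat, rot_deg = tr$rot, zoom = tr$zoom, shear_deg = tr$shear,
              hflip = tr$hflip, vflip = tr$vflip, crop = tr$crop,
              dx = tr$dx, dy = tr$dy, fill = fill)
}

#' Offline augmentation to a common per-class target count
#'
#' Brings every class of a *training* cohort up to exactly
#' `target_per_class` samples by adding augmented copies of randomly chosen
#' (with replacement) originals. Originals are always retained; augmented
#' copies inherit their source's label, and the manifest records the source
#' id and transform of every copy. Exposed borders of geometric transforms
#' are filled with the matrix's coldest value (the ambient background).
#' Apply this per fold, after splitting, and never to validation data.
#'
#' @param cohort a `labeled_cohort` (the training split of one fold).
#' @param policy an [augmentation_policy()].
#' @param target_per_class target count per class; default the largest
#'   class's count. Must be at least every current class count (no
#'   undersampling).
#' @param seed seed for the transform draws; default `policy$seed`.
#' @return a `labeled_cohort` with the augmented samples appended; its
#'   manifest gains `origin_id`, `transform` and `aug_seed` columns.
#' @export
offline_balance <- function(cohort, policy = augmentation_policy(),
                            target_per_class = NULL, seed = policy$seed) {
  stopifnot(inherits(cohort, "labeled_cohort"),
            inherits(policy, "augmentation_policy"))
  counts <- table(cohort$labels)
  if (is.null(target_per_class)) target_per_class <- max(counts)
  if (any(counts > target_per_class))
    stop(sprintf(
      "target_per_class (%d) below existing count of class %s (%d); undersampling is not supported",
      target_per_class, names(counts)[which.max(counts)], max(counts)))
  set.seed(seed)
  man <- cohort$manifest
  man$origin_id <- NA_character_
  man$transform <- NA_character_
  man$aug_seed <- NA_integer_
  new_t <- list(); new_lab <- integer(); new_tci <- numeric()
  new_truth <- list(); new_rows <- list()
  aug_i <- 0L
  for (cl in names(counts)) {
    n_add <- target_per_class - counts[[cl]]
    if (n_add == 0) next
    src_idx <- which(cohort$labels == as.integer(cl))
    picks <- sample(src_idx, n_add, replace = TRUE)
    for (s in picks) {
      aug_i <- aug_i + 1L
      src <- cohort$thermograms[[s]]
      tr <- draw_offline_transform(policy, c(src$height, src$width))
      m <- apply_offline_transform(src$temperatures, tr,
                                   fill = min(src$temperatures))
      sid <- sprintf("%s_aug%03d", src$subject_id, aug_i)
      new_t[[length(new_t) + 1L]] <-
        thermogram(m, subject_id = sid, side = src$side, group = src$group)
      new_lab <- c(new_lab, cohort$labels[s])
      new_tci <- c(new_tci, cohort$tci[s])
      new_truth[[length(new_truth) + 1L]] <- cohort$truths[[s]]
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        subject_id = sid, side = src$side, group = src$group,
        class = cohort$labels[s], tci_truth = cohort$tci[s],
        path = NA_character_, origin_id = src$subject_id,
        transform = tr$descriptor, aug_seed = seed, stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(new_rows) > 0) rbind(man, do.call(rbind, new_rows))
              else man
  rownames(manifest) <- NULL
  structure(list(thermograms = c(cohort$thermograms, new_t),
                 labels = c(cohort$labels, new_lab),
                 tci = c(cohort$tci, new_tci),
                 truths = c(cohort$truths, new_truth),
                 manifest = manifest, seed = cohort$seed),
            class = "labeled_cohort")
}

#' Online augmentation of an encoded input
#'
#' Draws one transform from the policy's online ranges and applies it:
#' small affine perturbation, brightness and contrast jitter, Gaussian
#' blur. The output has the input's shape and intensities clipped to
#' `[0, 1]`. Zero-width ranges give the identity.
#'
#' @param sample an `encoded_input` (see [encode_for_network()]) or a
#'   numeric matrix of intensities in `[0, 1]`.
#' @param policy an [augmentation_policy()].
#' @param seed optional seed for the draw.
#' @return object of the same type and shape as `sample`.
#' @export
online_augment <- function(sample, policy = augmentation_policy(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- if (inherits(sample, "encoded_input")) sample$values else sample
  rot <- stats::runif(1, policy$online_rotation[1], policy$online_rotation[2])
  zoom <- stats::runif(1, policy$online_zoom[1], policy$online_zoom[2])
  if (rot != 0 || zoom != 1)
    x <- warp_affine(x, rot_deg = rot, zoom = zoom, fill = 0)
  f <- stats::runif(1, policy$contrast[1], policy$contrast[2])
  if (f != 1) x <- (x - 0.5) * f + 0.5
  b <- stats::runif(1, policy$brightness[1], policy$brightness[2])
  if (b != 0) x <- x + b
  if (policy$blur_sigma > 0) {
    sig <- stats::runif(1, 0, policy$blur_sigma)
    x <- gaussian_blur(x, sig)
  }
  x <- clamp(x, 0, 1)
  if (inherits(sample, "encoded_input")) {
    sample$values <- x
    sample
  } else x
}
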