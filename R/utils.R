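# Shared numerical helpers: image resampling, affine warping, morphology.
# All operate on plain numeric/logical matrices; vectorized, no compiled code.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
round_half_away <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Bilinear resize of a numeric matrix
#'
#' Pixel-center convention: output pixel centers are mapped uniformly onto the
#' input extent, so resizing a matrix to its own size is an exact identity.
#' Suitable for continuous-valued images (temperatures, intensities).
#'
#' @param mat numeric matrix.
#' @param out_h,out_w output dimensions (positive integers).
#' @return numeric matrix of dimension `out_h` by `out_w`.
#' @keywords internal
#' @noRd
resize_bilinear <- function(mat, out_h, out_w) {
  H <- nrow(mat); W <- ncol(mat)
  stopifnot(H >= 1, W >= 1, out_h >= 1, out_w >= 1)
  py <- clamp((seq_len(out_h) - 0.5) * (H / out_h) + 0.5, 1, H)
  px <- clamp((seq_len(out_w) - 0.5) * (W / out_w) + 0.5, 1, W)
  y0 <- pmin(floor(py), H); y1 <- pmin(y0 + 1, H); wy <- py - y0
  x0 <- pmin(floor(px), W); x1 <- pmin(x0 + 1, W); wx <- px - x0
  Wy <- matrix(wy, out_h, out_w)
  Wx <- matrix(wx, out_h, out_w, byrow = TRUE)
  A00 <- mat[y0, x0, drop = FALSE]; A01 <- mat[y0, x1, drop = FALSE]
  A10 <- mat[y1, x0, drop = FALSE]; A11 <- mat[y1, x1, drop = FALSE]
  (1 - Wy) * ((1 - Wx) * A00 + Wx * A01) + Wy * ((1 - Wx) * A10 + Wx * A11)
}

# Bilinear sample `mat` at fractional (ys, xs); coordinates outside the image
# take `fill`. ys/xs are equal-length vectors in 1-based pixel coordinates.
#' @noRd
bilinear_sample <- function(mat, ys, xs, fill = 0) {
  H <- nrow(mat); W <- ncol(mat)
  valid <- ys >= 1 & ys <= H & xs >= 1 & xs <= W
  ysc <- clamp(ys, 1, H); xsc <- clamp(xs, 1, W)
  y0 <- pmin(floor(ysc), H); y1 <- pmin(y0 + 1, H); wy <- ysc - y0
  x0 <- pmin(floor(xsc), W); x1 <- pmin(x0 + 1, W); wx <- xsc - x0
  v <- (1 - wy) * ((1 - wx) * mat[cbind(y0, x0)] + wx * mat[cbind(y0, x1)]) +
    wy * ((1 - wx) * mat[cbind(y1, x0)] + wx * mat[cbind(y1, x1)])
  v[!valid] <- fill
  v
}

#' Affine warp of a matrix (rotation / zoom / shear / flip / crop / shift)
#'
#' Inverse-mapped warp with bilinear interpolation about the image center.
#' `crop` < 1 samples the central `crop` fraction (optionally offset by
#' `dx`/`dy` pixels) and rescales it to the full frame, i.e. a zoom-in crop.
#' With all parameters at their defaults the output equals the input exactly.
#'
#' @param mat numeric matrix.
#' @param rot_deg rotation angle, degrees, counter-clockwise.
#' @param zoom isotropic scale factor (>1 enlarges content).
#' @param shear_deg horizontal shear angle in degrees.
#' @param hflip,vflip mirror about the vertical / horizontal axis.
#' @param crop crop fraction in (0.5, 1].
#' @param dx,dy translation of the sampling window, pixels.
#' @param fill value for samples falling outside the source image.
#' @keywords internal
#' @noRd
warp_affine <- function(mat, rot_deg = 0, zoom = 1, shear_deg = 0,
                        hflip = FALSE, vflip = FALSE, crop = 1,
                        dx = 0, dy = 0, fill = 0) {
  H <- nrow(mat); W <- ncol(mat)
  identity_geom <- rot_deg == 0 && zoom == 1 && shear_deg == 0 &&
    !hflip && !vflip && crop == 1 && dx == 0 && dy == 0
  if (identity_geom) return(mat)
  z <- zoom / crop
  th <- rot_deg * pi / 180
  k <- tan(shear_deg * pi / 180)
  # forward: flip -> shear -> rotate -> scale; invert in reverse order
  Zinv <- diag(c(1 / z, 1 / z))
  Rinv <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  Shinv <- matrix(c(1, -k, 0, 1), 2, 2, byrow = TRUE)  # acts on (x, y)
  Fl <- diag(c(if (hflip) -1 else 1, if (vflip) -1 else 1))
  M <- Fl %*% Shinv %*% Rinv %*% Zinv
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  X <- matrix(seq_len(W) - cx, H, W, byrow = TRUE) - dx
  Y <- matrix(seq_len(H) - cy, H, W) - dy
  sx <- M[1, 1] * X + M[1, 2] * Y + cx
  sy <- M[2, 1] * X + M[2, 2] * Y + cy
  out <- bilinear_sample(mat, as.vector(sy), as.vector(sx), fill = fill)
  matrix(out, H, W)
}

# Shift a matrix by (dr, dc), padding with `fill`.
#' @noRd
shift_matrix <- function(m, dr, dc, fill) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Label 4-connected components of a logical mask by iterative minimum-label
# propagation. Returns an integer matrix (NA outside the mask) whose values
# are component representatives (smallest column-major index in the component).
#' @noRd
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(NA_real_, H, W)
  lab[mask] <- which(mask)
  if (!any(mask)) return(lab)
  repeat {
    nb <- pmin(shift_matrix(lab, 1, 0, NA), shift_matrix(lab, -1, 0, NA),
               shift_matrix(lab, 0, 1, NA), shift_matrix(lab, 0, -1, NA),
               na.rm = TRUE)
    new <- pmin(lab, nb, na.rm = TRUE)
    new[!mask] <- NA_real_
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# Keep only the largest 4-connected component (ties: smallest label).
#' @noRd
largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- label_components(mask)
  tab <- table(lab[mask])
  keep <- as.numeric(names(tab)[which.max(tab)])
  !is.na(lab) & lab == keep
}

# Fill holes: background cells not 4-connected to the image border become foot.
#' @noRd
fill_holes <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- !mask
  reach <- matrix(FALSE, H, W)
  reach[1, ] <- bg[1, ]; reach[H, ] <- bg[H, ]
  reach[, 1] <- bg[, 1]; reach[, W] <- bg[, W]
  repeat {
    grown <- bg & (reach |
                     shift_matrix(reach, 1, 0, FALSE) |
                     shift_matrix(reach, -1, 0, FALSE) |
                     shift_matrix(reach, 0, 1, FALSE) |
                     shift_matrix(reach, 0, -1, FALSE))
    if (identical(grown, reach)) break
    reach <- grown
  }
  mask | (bg & !reach)
}

# Separable Gaussian blur with edge replication; sigma <= 0 is the identity.
#' @noRd
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  acc <- matrix(0, nrow(mat), ncol(mat))
  for (i in seq_along(k)) acc <- acc + k[i] * shift_matrix_edge(mat, (-r:r)[i], 0)
  out <- acc
  acc <- matrix(0, nrow(mat), ncol(mat))
  for (i in seq_along(k)) acc <- acc + k[i] * shift_matrix_edge(out, 0, (-r:r)[i])
  acc
}

# Shift with edge replication (used by the blur only).
#' @noRd
shift_matrix_edge <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  ri <- clamp(seq_len(H) - dr, 1, H)
  ci <- clamp(seq_len(W) - dc, 1, W)
  m[ri, ci, drop = FALSE]
}
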