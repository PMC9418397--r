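# Compact convolutional network for thermogram grading.
#
# No deep-learning backend is assumed: convolution is implemented as
# im2col + GEMM in vectorized base R (the matrix products dominate the cost
# and go through BLAS), with ReLU, 2x2 max pooling, inverted dropout, a
# dense layer and a softmax head, trained by Adam on class-weighted
# cross-entropy. Activations are carried as (H*W*B) x C matrices with
# row-major order (row index varies fastest over image rows, then columns,
# then batch), which makes im2col a sequence of strided array extractions.

#' Network architecture settings
#'
#' The default is the rectangular-input architecture: 180 x 80 single-channel
#' input, three 3x3 convolution blocks (16, 32, 64 filters, each followed by
#' ReLU and 2x2 max pooling), dropout 0.5 before a 128-unit dense layer and
#' a softmax head. Filter counts and kernel sizes are an interpretation of
#' the published layer diagram, which does not state them numerically; all
#' are configurable here.
#'
#' @param input_shape `c(height, width)` of the encoded input.
#' @param n_classes 5 (diabetic grades only) or 6 (control included).
#' @param conv_filters integer vector, filters per convolution block.
#' @param kernel kernel sizes per block (recycled).
#' @param stride convolution strides per block (recycled).
#' @param pool pooling window (2 = halve after each block, 1 = none).
#' @param dense_units width of the fully-connected layer.
#' @param dropout dropout rate in `[0, 1)` applied before the dense layer's
#'   output during training.
#' @param class_levels class labels in output order; defaults to `0:5` for
#'   6 classes and `1:5` for 5.
#' @return a `network_config` list.
#' @export
network_config <- function(input_shape = c(180, 80), n_classes = 6,
                           conv_filters = c(16, 32, 64), kernel = 3,
                           stride = 1, pool = 2, dense_units = 128,
                           dropout = 0.5, class_levels = NULL) {
  stopifnot(n_classes %in% c(5, 6), dropout >= 0, dropout < 1,
            length(input_shape) == 2, all(conv_filters >= 1))
  if (is.null(class_levels))
    class_levels <- if (n_classes == 6) 0:5 else 1:5
  stopifnot(length(class_levels) == n_classes)
  nb <- length(conv_filters)
  structure(list(input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes),
                 conv_filters = as.integer(conv_filters),
                 kernel = rep_len(as.integer(kernel), nb),
                 stride = rep_len(as.integer(stride), nb),
                 pool = as.integer(pool),
                 dense_units = as.integer(dense_units), dropout = dropout,
                 class_levels = class_levels),
            class = "network_config")
}

#' AlexNet-style square-input variant
#'
#' A compact from-scratch stand-in for the classical 227 x 227 square-input
#' architecture (large first kernel, stride 4), used for the resized/padded
#' input comparison. Pretrained initialization is not supported (it would
#' require an external weight download); the network trains from scratch.
#'
#' @inheritParams network_config
#' @export
alexnet_style_config <- function(n_classes = 6, dropout = 0.5) {
  network_config(input_shape = c(227, 227), n_classes = n_classes,
                 conv_filters = c(16, 32, 48), kernel = c(11, 5, 3),
                 stride = c(4, 1, 1), pool = 2, dense_units = 128,
                 dropout = dropout)
}

#' Training settings
#'
#' Optimizer hyperparameters are package defaults (Adam, learning rate 1e-3,
#' batch 32, 30 epochs); the source method does not publish its values.
#'
#' @param epochs number of passes over the training data (>= 1).
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param class_weights optional per-class loss weights (length = number of
#'   classes, in `class_levels` order); e.g. [inverse_frequency_weights()].
#' @param augment_policy optional [augmentation_policy()] applied online to
#'   every training sample, each epoch.
#' @param seed RNG seed covering initial shuffling, dropout and online
#'   augmentation.
#' @param verbose print one line per epoch.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 30, batch_size = 32, lr = 1e-3,
                         class_weights = NULL, augment_policy = NULL,
                         seed = 1, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 class_weights = class_weights,
                 augment_policy = augment_policy, seed = seed,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Build (initialize) a network
#'
#' He-normal initialization for convolution and dense weights, zeros for
#' biases. The same configuration and seed always produce identical initial
#' weights.
#'
#' @param cfg a [network_config()].
#' @param seed initialization seed.
#' @return object of class `thermo_cnn`.
#' @export
build_network <- function(cfg = network_config(), seed = 1) {
  stopifnot(inherits(cfg, "network_config"))
  set.seed(seed)
  H <- cfg$input_shape[1]; W <- cfg$input_shape[2]
  params <- list()
  dims <- list()
  cin <- 1L
  for (i in seq_along(cfg$conv_filters)) {
    k <- cfg$kernel[i]; s <- cfg$stride[i]; cout <- cfg$conv_filters[i]
    p <- k %/% 2L
    Hc <- (H + 2L * p - k) %/% s + 1L
    Wc <- (W + 2L * p - k) %/% s + 1L
    fan_in <- k * k * cin
    params[[sprintf("conv%d_W", i)]] <-
      matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
    params[[sprintf("conv%d_b", i)]] <- numeric(cout)
    Hp <- if (cfg$pool > 1) Hc %/% cfg$pool else Hc
    Wp <- if (cfg$pool > 1) Wc %/% cfg$pool else Wc
    dims[[i]] <- list(H = H, W = W, cin = cin, cout = cout, k = k, s = s,
                      p = p, Hc = Hc, Wc = Wc, Hp = Hp, Wp = Wp)
    H <- Hp; W <- Wp; cin <- cout
  }
  n_feat <- H * W * cin
  if (n_feat < 1) stop("input shape too small for this architecture")
  params$dense_W <- matrix(stats::rnorm(cfg$dense_units * n_feat, 0,
                                        sqrt(2 / n_feat)),
                           cfg$dense_units, n_feat)
  params$dense_b <- numeric(cfg$dense_units)
  params$out_W <- matrix(stats::rnorm(cfg$n_classes * cfg$dense_units, 0,
                                      sqrt(1 / cfg$dense_units)),
                         cfg$n_classes, cfg$dense_units)
  params$out_b <- numeric(cfg$n_classes)
  structure(list(config = cfg, params = params, dims = dims,
                 n_features = n_feat, seed = seed, trained = FALSE,
                 input_center = 0, input_scale = 1, history = NULL),
            class = "thermo_cnn")
}

#' Number of trainable parameters
#' @param model a `thermo_cnn`.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, numeric(1)))

#' @export
print.thermo_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<thermo_cnn> input %dx%d, %d classes, conv [%s], dense %d, dropout %.2f\n",
              cfg$input_shape[1], cfg$input_shape[2], cfg$n_classes,
              paste(cfg$conv_filters, collapse = ", "), cfg$dense_units,
              cfg$dropout))
  cat(sprintf("  %d parameters, %s\n", n_parameters(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# --- internal layer machinery -------------------------------------------
#
# im2col / col2im (with implicit zero padding) and 2x2 max pooling are
# compiled (src/conv_ops.cpp); the matrix products go through BLAS.

#' @noRd
conv_forward <- function(A, d, B, Wmat, b, keep_cache = FALSE) {
  cols <- im2col_pad(A, d$H, d$W, B, d$cin, d$k, d$s, d$p, d$Hc, d$Wc)
  Z <- cols %*% Wmat
  for (j in seq_len(ncol(Z))) Z[, j] <- Z[, j] + b[j]
  list(Z = Z, cols = if (keep_cache) cols else NULL)
}

#' @noRd
conv_backward <- function(dZ, cols, Wmat, d, B, need_dx) {
  dW <- crossprod(cols, dZ)
  db <- colSums(dZ)
  dX <- NULL
  if (need_dx) {
    dcols <- tcrossprod(dZ, Wmat)
    dX <- col2im_pad(dcols, d$H, d$W, B, d$cin, d$k, d$s, d$p, d$Hc, d$Wc)
  }
  list(dW = dW, db = db, dX = dX)
}

#' @noRd
pool_forward <- function(A, H, W, B, C) {
  pf <- pool2_forward(A, H, W, B, C)
  list(out = pf$out, idx = pf$idx, in_rows = H * W * B)
}

#' @noRd
pool_backward <- function(dOut, cache) {
  pool2_backward(dOut, cache$idx, cache$in_rows)
}

# flatten (oh*ow*B) x C -> features x B, channel-slowest feature order
#' @noRd
flatten_fwd <- function(A, oh, ow, B, C) {
  dim(A) <- c(oh, ow, B, C)
  A <- aperm(A, c(1, 2, 4, 3))
  dim(A) <- c(oh * ow * C, B)
  A
}

#' @noRd
flatten_bwd <- function(dF, oh, ow, B, C) {
  dim(dF) <- c(oh, ow, C, B)
  dF <- aperm(dF, c(1, 2, 4, 3))
  dim(dF) <- c(oh * ow * B, C)
  dF
}

#' @noRd
softmax_cols <- function(L) {
  L <- sweep(L, 2, apply(L, 2, max), "-")
  E <- exp(L)
  sweep(E, 2, colSums(E), "/")
}

# Full forward pass. X: array (H, W, B). Returns probabilities (K x B) and,
# when `train`, the caches needed for backprop.
#' @noRd
cnn_forward <- function(model, X, params = model$params, train = FALSE) {
  cfg <- model$config
  dm <- dim(X)
  if (length(dm) == 2) dim(X) <- c(dm, 1L)
  dm <- dim(X)
  if (dm[1] != cfg$input_shape[1] || dm[2] != cfg$input_shape[2])
    stop(sprintf("shape error: input %dx%d does not match network input %dx%d",
                 dm[1], dm[2], cfg$input_shape[1], cfg$input_shape[2]))
  B <- dm[3]
  A <- matrix((as.vector(X) - model$input_center) / model$input_scale,
              ncol = 1L)
  caches <- list()
  for (i in seq_along(cfg$conv_filters)) {
    d <- model$dims[[i]]
    cf <- conv_forward(A, d, B, params[[sprintf("conv%d_W", i)]],
                       params[[sprintf("conv%d_b", i)]], keep_cache = train)
    relu_mask <- cf$Z > 0
    A <- cf$Z * relu_mask
    if (cfg$pool > 1) {
      pc <- pool_forward(A, d$Hc, d$Wc, B, d$cout)
      A <- pc$out
    } else pc <- NULL
    caches[[i]] <- list(cols = cf$cols, relu = relu_mask, pool = pc, d = d)
  }
  dlast <- model$dims[[length(model$dims)]]
  Fm <- flatten_fwd(A, dlast$Hp, dlast$Wp, B, dlast$cout)
  Z1 <- params$dense_W %*% Fm + params$dense_b
  A1 <- Z1 * (Z1 > 0)
  drop_mask <- NULL
  A1d <- A1
  if (train && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    drop_mask <- matrix((stats::runif(length(A1)) < keep) / keep,
                        nrow(A1), ncol(A1))
    A1d <- A1 * drop_mask
  }
  logits <- params$out_W %*% A1d + params$out_b
  probs <- softmax_cols(logits)
  if (!train) return(list(probs = probs))
  list(probs = probs, caches = caches, Fm = Fm, Z1 = Z1, A1d = A1d,
       drop_mask = drop_mask, B = B)
}

# Weighted cross-entropy loss + full gradient for one batch.
#' @noRd
cnn_loss_grad <- function(model, params, X, yidx, w_class) {
  fw <- cnn_forward(model, X, params = params, train = TRUE)
  B <- fw$B
  K <- model$config$n_classes
  wvec <- w_class[yidx]
  py <- fw$probs[cbind(yidx, seq_len(B))]
  loss <- -mean(wvec * log(pmax(py, 1e-12)))
  acc <- mean(max.col(t(fw$probs), ties.method = "first") == yidx)
  dlog <- fw$probs
  dlog[cbind(yidx, seq_len(B))] <- dlog[cbind(yidx, seq_len(B))] - 1
  dlog <- dlog * rep(wvec / B, each = K)
  g <- list()
  g$out_W <- tcrossprod(dlog, fw$A1d)
  g$out_b <- rowSums(dlog)
  dA1d <- crossprod(params$out_W, dlog)
  dA1 <- if (is.null(fw$drop_mask)) dA1d else dA1d * fw$drop_mask
  dZ1 <- dA1 * (fw$Z1 > 0)
  g$dense_W <- tcrossprod(dZ1, fw$Fm)
  g$dense_b <- rowSums(dZ1)
  dFm <- crossprod(params$dense_W, dZ1)
  dlast <- model$dims[[length(model$dims)]]
  dA <- flatten_bwd(dFm, dlast$Hp, dlast$Wp, B, dlast$cout)
  for (i in rev(seq_along(model$dims))) {
    cache <- fw$caches[[i]]
    if (!is.null(cache$pool)) dA <- pool_backward(dA, cache$pool)
    dZ <- dA * cache$relu
    cb <- conv_backward(dZ, cache$cols, params[[sprintf("conv%d_W", i)]],
                        cache$d, B, need_dx = i > 1)
    g[[sprintf("conv%d_W", i)]] <- cb$dW
    g[[sprintf("conv%d_b", i)]] <- cb$db
    dA <- cb$dX
  }
  list(loss = loss, acc = acc, grads = g)
}

#' Train a network
#'
#' Minimizes class-weighted cross-entropy with Adam. The history records
#' per-epoch training/validation loss and accuracy; if validation data is
#' supplied, the weights with the best validation accuracy are retained.
#'
#' @param model a [build_network()] result.
#' @param x training inputs: numeric array `c(H, W, N)` (see
#'   [stack_encoded()]).
#' @param y training labels (values in the model's `class_levels`).
#' @param x_val,y_val optional validation inputs/labels (never augmented).
#' @param config a [train_config()].
#' @return the trained `thermo_cnn` with elements `history` (data.frame) and
#'   `trained = TRUE`.
#' @export
train_network <- function(model, x, y, x_val = NULL, y_val = NULL,
                          config = train_config()) {
  stopifnot(inherits(model, "thermo_cnn"), inherits(config, "train_config"))
  levels <- model$config$class_levels
  K <- model$config$n_classes
  N <- dim(x)[3]
  if (is.null(N) || N == 0 || length(y) == 0) stop("empty training set")
  if (length(y) != N) stop("length(y) must equal the number of inputs")
  yidx <- match(y, levels)
  if (anyNA(yidx)) stop("labels outside the model's class range")
  w_class <- config$class_weights
  if (is.null(w_class)) w_class <- rep(1, K)
  if (length(w_class) != K) stop("class_weights must have length ", K)
  yv <- NULL
  if (!is.null(x_val)) {
    yv <- match(y_val, levels)
    if (anyNA(yv)) stop("validation labels outside the model's class range")
  }
  set.seed(config$seed)
  # standardize inputs on the training set (stored in the model so that
  # inference applies the identical transform); He-initialized layers
  # expect roughly unit-variance inputs
  if (!model$trained) {
    model$input_center <- mean(x)
    model$input_scale <- max(stats::sd(x), 1e-6)
  }
  params <- model$params
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  best_acc <- -Inf
  best_params <- params
  hist <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    perm <- sample(N)
    starts <- seq(1L, N, by = config$batch_size)
    ep_loss <- 0; ep_acc <- 0; ep_n <- 0L
    for (s0 in starts) {
      sel <- perm[s0:min(s0 + config$batch_size - 1L, N)]
      Xb <- x[, , sel, drop = FALSE]
      if (!is.null(config$augment_policy)) {
        for (j in seq_along(sel))
          Xb[, , j] <- online_augment(Xb[, , j], config$augment_policy)
      }
      lg <- cnn_loss_grad(model, params, Xb, yidx[sel], w_class)
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite loss at epoch %d; aborting (consider a lower learning rate)", ep))
      step <- step + 1L
      for (nm in names(params)) {
        gmat <- lg$grads[[nm]]
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gmat
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gmat^2
        mhat <- mstate[[nm]] / (1 - b1^step)
        vhat <- vstate[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - config$lr * mhat / (sqrt(vhat) + eps)
      }
      nb <- length(sel)
      ep_loss <- ep_loss + lg$loss * nb
      ep_acc <- ep_acc + lg$acc * nb
      ep_n <- ep_n + nb
    }
    val_loss <- NA_real_; val_acc <- NA_real_
    if (!is.null(x_val)) {
      nv <- length(yv)
      pv <- matrix(NA_real_, K, nv)
      for (v0 in seq(1L, nv, by = 64L)) {
        vsel <- v0:min(v0 + 63L, nv)
        pv[, vsel] <- cnn_forward(model, x_val[, , vsel, drop = FALSE],
                                  params = params, train = FALSE)$probs
      }
      val_loss <- -mean(log(pmax(pv[cbind(yv, seq_along(yv))], 1e-12)))
      val_acc <- mean(max.col(t(pv), ties.method = "first") == yv)
      if (val_acc > best_acc) {
        best_acc <- val_acc
        best_params <- params
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / ep_n,
                             train_acc = ep_acc / ep_n, val_loss = val_loss,
                             val_acc = val_acc)
    if (config$verbose)
      message(sprintf("epoch %d: loss %.4f acc %.4f val_acc %s", ep,
                      ep_loss / ep_n, ep_acc / ep_n, format(val_acc)))
  }
  model$params <- if (!is.null(x_val)) best_params else params
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

#' Predict labels and class probabilities
#'
#' Inference is deterministic: dropout is disabled and argmax ties resolve
#' to the first class.
#'
#' @param object a trained `thermo_cnn`.
#' @param x numeric array `c(H, W, N)` (a single `c(H, W)` matrix is
#'   accepted).
#' @param batch_size internal forward batch size.
#' @param ... unused.
#' @return list with `labels` (in the model's class levels) and `probs`
#'   (N x K matrix).
#' @export
predict.thermo_cnn <- function(object, x, batch_size = 64, ...) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  N <- dim(x)[3]
  probs <- matrix(NA_real_, N, object$config$n_classes)
  for (s0 in seq(1L, N, by = batch_size)) {
    sel <- s0:min(s0 + batch_size - 1L, N)
    p <- cnn_forward(object, x[, , sel, drop = FALSE], train = FALSE)$probs
    probs[sel, ] <- t(p)
  }
  colnames(probs) <- as.character(object$config$class_levels)
  labels <- object$config$class_levels[max.col(probs, ties.method = "first")]
  list(labels = labels, probs = probs)
}

#' Stack encoded inputs into a network batch
#'
#' @param inputs list of `encoded_input` objects (or numeric matrices) of
#'   identical shape.
#' @return numeric array `c(H, W, N)`.
#' @export
stack_encoded <- function(inputs) {
  mats <- lapply(inputs, function(e)
    if (inherits(e, "encoded_input")) e$values else e)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop("all encoded inputs must share one shape")
  array(unlist(mats, use.names = FALSE), c(d, length(mats)))
}
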