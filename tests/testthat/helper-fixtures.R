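# Shared fixtures: all inputs are built in code at test time.

make_uniform_thermo <- function(value = 26, h = 20, w = 10,
                                side = "right", group = "diabetic",
                                subject_id = "fix") {
  thermogram(matrix(value, h, w), subject_id = subject_id,
             side = side, group = group)
}

# small architecture used wherever training speed matters more than scale
tiny_net_cfg <- function(n_classes = 5, input_shape = c(16, 8)) {
  network_config(input_shape = input_shape, n_classes = n_classes,
                 conv_filters = c(4, 8), dense_units = 16, dropout = 0.2)
}

# two-class, trivially separable toy batch: constant-intensity images
toy_separable <- function(n_per_class = 20, h = 16, w = 8, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- array(0, c(h, w, n))
  y <- integer(n)
  for (i in seq_len(n)) {
    cls <- (i - 1) %% 2
    x[, , i] <- matrix(ifelse(cls == 0, 0.2, 0.8), h, w) +
      matrix(rnorm(h * w, 0, 0.02), h, w)
    y[i] <- cls + 1L  # classes 1 and 2 of a 5-class head
  }
  list(x = clamp_01(x), y = y)
}

clamp_01 <- function(x) pmin(pmax(x, 0), 1)

# brute-force one-vs-rest metrics by explicit enumeration over samples
oracle_classwise <- function(y_true, y_pred, levels) {
  N <- length(y_true)
  do.call(rbind, lapply(levels, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    tn <- sum(y_true != cl & y_pred != cl)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
      2 * prec * sens / (prec + sens) else NA_real_
    data.frame(class = cl, accuracy = (tp + tn) / N, specificity = spec,
               sensitivity = sens, precision = prec, f_measure = f)
  }))
}
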