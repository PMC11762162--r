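#' Coarse-to-fine landmark cascade
#'
#' A cascade detector is an ordered list of stages; stage k sees a window of
#' `shrink^(k-1)` times the ROI size centered on the previous estimate and
#' refines the landmark. Each stage is a function
#' `function(win, end)` returning a point in the window's own crop
#' coordinates, where `win` is a list with the window's `img`, this tooth's
#' `mask`, the all-teeth foreground `fg`, the mesio-distal `axis`, the
#' global `offset` and the jaw `profile`, and `end` is `"min"` or `"max"`
#' (which arc extreme of the tooth is being located). A single-stage
#' cascade of the geometric reference stage is identical to
#' [reference_landmark_backend()].
#'
#' @param stages list of stage functions, or an integer: that many copies of
#'   the reference stage.
#' @param shrink per-stage window shrink factor in (0, 1].
#' @return object of class `cascade_detector`.
#' @export
cascade_detector <- function(stages = 3L, shrink = 0.6) {
  if (is.numeric(stages))
    stages <- lapply(seq_len(as.integer(stages)), function(i) reference_stage())
  if (!length(stages)) stop("at least one stage is required")
  if (shrink <= 0 || shrink > 1) stop("shrink must be in (0, 1]")
  structure(list(stages = stages, shrink = shrink),
            class = "cascade_detector")
}

#' The geometric reference stage
#'
#' Returns the interproximal extreme of the tooth along the mesio-distal
#' axis within the current window (the classical per-stage predictor used
#' when no trained stage is supplied).
#'
#' @return a stage function for [cascade_detector()].
#' @export
reference_stage <- function() {
  function(win, end) {
    # a window with marginal mask support cannot estimate the projection
    # profile; keep the previous estimate (the window center) instead
    if (sum(win$mask) < 25)
      return(c((nrow(win$mask) + 1) / 2, (ncol(win$mask) + 1) / 2))
    interproximal_extreme(win, end)
  }
}

#' Run a landmark cascade on a tooth ROI
#'
#' Runs the stage list once per landmark end. Stage k crops a window of
#' `shrink^(k-1)` times the ROI size centered on the previous estimate
#' (clipped to the ROI) and refines; an estimate that exits the ROI is
#' clamped to its boundary and the pair flagged low-confidence. The final
#' estimates are returned in ROI crop coordinates, like
#' [reference_landmark_backend()].
#'
#' @param detector a [cascade_detector()].
#' @param roi a `tooth_roi`.
#' @return a `landmark_pair`.
#' @export
run_cascade <- function(detector, roi) {
  stopifnot(inherits(detector, "cascade_detector"), inherits(roi, "tooth_roi"))
  d <- dim(roi$img)
  flag <- ""
  one_end <- function(end) {
    est <- c((d[1] + 1) / 2, (d[2] + 1) / 2)
    for (k in seq_along(detector$stages)) {
      f <- detector$shrink^(k - 1)
      hw <- pmax(2, f * d / 2)
      x1 <- max(1L, floor(est[1] - hw[1])); x2 <- min(d[1], ceiling(est[1] + hw[1]))
      y1 <- max(1L, floor(est[2] - hw[2])); y2 <- min(d[2], ceiling(est[2] + hw[2]))
      win <- roi_window(roi,
                        img = roi$img[x1:x2, y1:y2, drop = FALSE],
                        mask = roi$mask[x1:x2, y1:y2, drop = FALSE],
                        fg = roi$fg[x1:x2, y1:y2, drop = FALSE],
                        extra_offset = c(x1 - 1L, y1 - 1L))
      p <- detector$stages[[k]](win, end)
      est <- c(p[1] + x1 - 1, p[2] + y1 - 1)
      if (est[1] < 1 || est[1] > d[1] || est[2] < 1 || est[2] > d[2]) {
        est <- clamp(est, c(1, 1), d)
        flag <<- "low_confidence"
      }
    }
    est
  }
  structure(list(lo = one_end("min"), hi = one_end("max"),
                 offset = roi$offset, axis = roi$axis,
                 backend = "cascade", depth = length(detector$stages),
                 flag = flag),
            class = "landmark_pair")
}

#' Landmark mean-squared-error loss
#'
#' `L = sum((A - Y)^2) / n` over the `n` predicted coordinates -- zero
#' exactly when every prediction equals its label.
#'
#' @param A predictions.
#' @param Y labels (same shape as `A`).
#' @return the scalar loss.
#' @export
landmark_mse <- function(A, Y) {
  A <- as.numeric(A); Y <- as.numeric(Y)
  if (length(A) != length(Y)) stop("A and Y differ in length")
  sum((A - Y)^2) / length(A)
}

#' One SGD-with-momentum update
#'
#' `v' = momentum * v + g`, `theta' = theta - eta * v'`. With zero momentum
#' this is the plain gradient step `theta - eta * g`.
#'
#' @param theta parameter vector/matrix.
#' @param grad gradient of the loss at `theta`.
#' @param velocity running velocity (same shape; zeros initially).
#' @param eta learning rate.
#' @param momentum momentum coefficient in \[0, 1).
#' @return list with updated `theta` and `velocity`.
#' @export
sgdm_step <- function(theta, grad, velocity = NULL, eta = 0.001,
                      momentum = 0.95) {
  if (is.null(velocity)) velocity <- theta * 0
  velocity <- momentum * velocity + grad
  list(theta = theta - eta * velocity, velocity = velocity)
}

# average-pool an image to pool x pool features in [0, 1]
pool_features <- function(img, pool = 16L) {
  d <- dim(img)
  bi <- ceiling(seq_len(d[1]) / d[1] * pool)
  bj <- ceiling(seq_len(d[2]) / d[2] * pool)
  idx <- cbind(rep(bi, times = d[2]), rep(bj, each = d[1]))
  acc <- tapply(as.numeric(img), list(factor(idx[, 1], 1:pool),
                                      factor(idx[, 2], 1:pool)), mean)
  acc[is.na(acc)] <- 0
  rng <- range(acc)
  if (diff(rng) > 0) acc <- (acc - rng[1]) / diff(rng)
  as.numeric(acc)
}

#' Train a cascade stage by minibatch SGD with momentum
#'
#' Fits a trainable landmark regressor (an average-pooled linear regressor;
#' the pooling size is configurable) on (crop, true landmark) examples by
#' minibatch stochastic gradient descent with momentum: the loss is the
#' landmark mean squared error and each update is
#' `theta <- theta - eta * (momentum * v + grad)`, with batch size 64,
#' learning rate 0.001 and momentum 0.95 by default. Crops are pooled to
#' `pool^2` features and landmark targets are normalized to the unit square
#' of their crop, so training is size-independent; the returned stage maps
#' its prediction back to window pixel coordinates.
#'
#' @param examples list of `list(crop = <matrix>, landmark = c(x, y))` with
#'   the landmark in 1-based crop pixel coordinates.
#' @param batch_size minibatch size m (an error is raised with fewer than
#'   `m` examples).
#' @param eta learning rate.
#' @param momentum momentum coefficient.
#' @param epochs passes over the training set.
#' @param pool pooled feature grid side.
#' @param seed RNG seed for shuffling.
#' @return object of class `cascade_stage`: the stage `fn` usable in
#'   [cascade_detector()], the weights, and the per-epoch `loss` trace
#'   (element 1 is the loss at initialization).
#' @export
train_cascade_stage <- function(examples, batch_size = 64L, eta = 0.001,
                                momentum = 0.95, epochs = 30L, pool = 16L,
                                seed = 1L) {
  m <- as.integer(batch_size)
  if (length(examples) < m)
    stop("need at least m = ", m, " examples, got ", length(examples))
  X <- t(vapply(examples, function(e) c(pool_features(e$crop, pool), 1),
                numeric(pool^2 + 1L)))
  Y <- t(vapply(examples, function(e) {
    d <- dim(e$crop)
    c(e$landmark[1] / d[1], e$landmark[2] / d[2])
  }, numeric(2)))
  p <- ncol(X)
  W <- matrix(0, p, 2)
  V <- matrix(0, p, 2)
  loss_trace <- landmark_mse(X %*% W, Y)
  n <- nrow(X)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (b in seq_len(floor(n / m))) {
        ii <- ord[((b - 1L) * m + 1L):(b * m)]
        Xb <- X[ii, , drop = FALSE]; Yb <- Y[ii, , drop = FALSE]
        err <- Xb %*% W - Yb
        grad <- 2 * t(Xb) %*% err / length(Yb)
        st <- sgdm_step(W, grad, V, eta, momentum)
        W <- st$theta; V <- st$velocity
      }
      loss_trace <- c(loss_trace, landmark_mse(X %*% W, Y))
    }
  })
  fn <- function(win, end) {
    x <- c(pool_features(win$img, pool), 1)
    pred <- as.numeric(x %*% W)
    c(pred[1] * nrow(win$img), pred[2] * ncol(win$img))
  }
  structure(list(fn = fn, weights = W, loss = loss_trace, pool = pool,
                 batch_size = m, eta = eta, momentum = momentum),
            class = "cascade_stage")
}

#' @export
print.cascade_stage <- function(x, ...) {
  cat(sprintf("<cascade_stage> pooled-linear, loss %.4g -> %.4g over %d epochs\n",
              x$loss[1], x$loss[length(x$loss)], length(x$loss) - 1L))
  invisible(x)
}
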