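## 1D convolutional network for classifying PCA score vectors.
##
## Architecture: `conv_layers` blocks of (valid 1D convolution, width
## `kernel_width`, stride 1 -> ReLU -> max-pool 2), a dense ReLU layer of
## `dense_units`, and a 2-class softmax head trained with cross-entropy and
## Adam. The second convolution block doubles the kernel count of the first.
## Implemented directly in matrix algebra (im2col patches); gradients are
## verified against numerical differentiation in the test suite.

cnn_shapes <- function(input_len, conv_layers, kernels, kernel_width) {
  len <- input_len; ch <- 1L; out <- list()
  for (l in seq_len(conv_layers)) {
    k <- kernels * 2L^(l - 1L)
    if (len < kernel_width) {
      stop("input too short for ", conv_layers, " convolution block(s): ",
           "length ", len, " < kernel width ", kernel_width, " at block ", l)
    }
    len <- len - kernel_width + 1L   # valid convolution
    len <- len %/% 2L                # max-pool 2
    if (len < 1L) stop("input too short: pooled length 0 at block ", l)
    out[[l]] <- list(k_in = ch, k_out = k)
    ch <- k
  }
  list(conv = out, flat = len * ch, final_len = len, final_ch = ch)
}

cnn_init <- function(input_len, conv_layers = 2L, kernels = 16L,
                     kernel_width = 7L, dense_units = 64L, n_classes = 2L) {
  sh <- cnn_shapes(input_len, conv_layers, kernels, kernel_width)
  conv <- lapply(sh$conv, function(s) {
    fan_in <- s$k_in * kernel_width
    list(W = array(stats::rnorm(s$k_out * s$k_in * kernel_width,
                                0, sqrt(2 / fan_in)),
                   dim = c(s$k_out, s$k_in, kernel_width)),
         b = rep(0, s$k_out))
  })
  list(conv = conv,
       W1 = matrix(stats::rnorm(sh$flat * dense_units, 0, sqrt(2 / sh$flat)),
                   sh$flat, dense_units),
       b1 = rep(0, dense_units),
       W2 = matrix(stats::rnorm(dense_units * n_classes, 0,
                                sqrt(2 / dense_units)),
                   dense_units, n_classes),
       b2 = rep(0, n_classes),
       kernel_width = kernel_width, input_len = input_len,
       conv_layers = conv_layers)
}

## a: n x T x C array -> patches and linear response of one conv layer
conv1d_forward <- function(a, W, b) {
  dn <- dim(a); n <- dn[1]; len <- dn[2]; ch <- dn[3]
  kw <- dim(W)[3]; k_out <- dim(W)[1]
  t_out <- len - kw + 1L
  P <- matrix(0, n * t_out, ch * kw)
  for (w in seq_len(kw)) for (c in seq_len(ch)) {
    P[, (w - 1L) * ch + c] <- as.vector(a[, w:(w + t_out - 1L), c])
  }
  Wm <- matrix(0, ch * kw, k_out)
  for (w in seq_len(kw)) for (c in seq_len(ch)) {
    Wm[(w - 1L) * ch + c, ] <- W[, c, w]
  }
  Z <- P %*% Wm
  Z <- sweep(Z, 2, b, "+")
  list(z = array(Z, c(n, t_out, k_out)), P = P, Wm = Wm, in_dim = dn)
}

conv1d_backward <- function(cache, dz, W) {
  dn <- cache$in_dim; n <- dn[1]; ch <- dn[3]
  kw <- dim(W)[3]; k_out <- dim(W)[1]
  t_out <- dim(dz)[2]
  dZm <- matrix(dz, n * t_out, k_out)
  dWm <- crossprod(cache$P, dZm)
  db <- colSums(dZm)
  dP <- tcrossprod(dZm, cache$Wm)
  da <- array(0, dn)
  for (w in seq_len(kw)) for (c in seq_len(ch)) {
    da[, w:(w + t_out - 1L), c] <- da[, w:(w + t_out - 1L), c] +
      matrix(dP[, (w - 1L) * ch + c], n, t_out)
  }
  dW <- array(0, dim(W))
  for (w in seq_len(kw)) for (c in seq_len(ch)) {
    dW[, c, w] <- dWm[(w - 1L) * ch + c, ]
  }
  list(dW = dW, db = db, da = da)
}

pool2_forward <- function(a) {
  dn <- dim(a); t_out <- dn[2] %/% 2L
  i1 <- seq(1L, 2L * t_out, by = 2L)
  a1 <- a[, i1, , drop = FALSE]
  a2 <- a[, i1 + 1L, , drop = FALSE]
  first <- a1 >= a2
  list(out = ifelse(first, a1, a2), first = first, in_dim = dn, t_out = t_out)
}

pool2_backward <- function(cache, dz) {
  da <- array(0, cache$in_dim)
  t_out <- cache$t_out
  i1 <- seq(1L, 2L * t_out, by = 2L)
  da[, i1, ] <- ifelse(cache$first, dz, 0)
  da[, i1 + 1L, ] <- ifelse(cache$first, 0, dz)
  da
}

cnn_forward <- function(params, x) {
  n <- nrow(x)
  a <- array(x, c(n, ncol(x), 1L))
  caches <- vector("list", length(params$conv))
  for (l in seq_along(params$conv)) {
    cv <- conv1d_forward(a, params$conv[[l]]$W, params$conv[[l]]$b)
    r <- pmax(cv$z, 0)
    pl <- pool2_forward(r)
    caches[[l]] <- list(conv = cv, relu_mask = cv$z > 0, pool = pl)
    a <- pl$out
  }
  flat <- matrix(a, n, prod(dim(a)[2:3]))
  h_pre <- sweep(flat %*% params$W1, 2, params$b1, "+")
  h <- pmax(h_pre, 0)
  logits <- sweep(h %*% params$W2, 2, params$b2, "+")
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, logits = logits, h = h, h_pre = h_pre, flat = flat,
       flat_dim = dim(a), caches = caches)
}

## y: n x 2 one-hot. Returns mean cross-entropy and all gradients.
cnn_backward <- function(params, fw, y) {
  n <- nrow(y)
  dlogits <- (fw$probs - y) / n
  dW2 <- crossprod(fw$h, dlogits)
  db2 <- colSums(dlogits)
  dh <- tcrossprod(dlogits, params$W2) * (fw$h_pre > 0)
  dW1 <- crossprod(fw$flat, dh)
  db1 <- colSums(dh)
  dflat <- tcrossprod(dh, params$W1)
  da <- array(dflat, fw$flat_dim)
  grads_conv <- vector("list", length(params$conv))
  for (l in rev(seq_along(params$conv))) {
    cache <- fw$caches[[l]]
    dr <- pool2_backward(cache$pool, da)
    dz <- dr * cache$relu_mask
    g <- conv1d_backward(cache$conv, dz, params$conv[[l]]$W)
    grads_conv[[l]] <- list(dW = g$dW, db = g$db)
    da <- g$da
  }
  list(conv = grads_conv, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

cnn_loss <- function(probs, y) {
  -mean(rowSums(y * log(pmax(probs, 1e-12))))
}

adam_step <- function(state, param, grad, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(state)) state <- list(m = param * 0, v = param * 0)
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train the 1D convolutional network
#'
#' @param x Numeric feature matrix (spectra in rows; typically PCA scores).
#'   Columns are standardized internally; the scaling is stored in the model.
#' @param y Factor or character vector of outcome labels.
#' @param conv_layers Number of convolution blocks (1 or 2).
#' @param kernels Kernels in the first block (the second block uses twice as
#'   many).
#' @param kernel_width Convolution kernel width (default 7).
#' @param dense_units Dense-layer width (default 64).
#' @param epochs Training epochs (default 40).
#' @param batch_size Minibatch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param validation Optional list(x, y) monitored for early stopping.
#' @param patience Early-stopping patience in epochs (default 8; only used
#'   when `validation` is given).
#' @param seed RNG seed for initialization and shuffling.
#' @return Object of class `cnn1d_model`.
#' @export
train_cnn <- function(x, y, conv_layers = 2L, kernels = 16L,
                      kernel_width = 7L, dense_units = 64L, epochs = 40L,
                      batch_size = 32L, lr = 1e-3, validation = NULL,
                      patience = 8L, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = outcome_levels())
  if (anyNA(y)) stop("labels outside the two-class outcome set")
  set.seed(seed)
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd); scale_[scale_ < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  yoh <- cbind(y == outcome_levels()[1], y == outcome_levels()[2]) * 1
  params <- cnn_init(ncol(x), conv_layers, kernels, kernel_width, dense_units)
  opt <- list(); t_step <- 0
  best <- list(loss = Inf, params = params, bad = 0L)
  n <- nrow(xs)
  for (ep in seq_len(epochs)) {
    idx <- sample(n)
    for (start in seq(1, n, by = batch_size)) {
      bi <- idx[start:min(start + batch_size - 1, n)]
      if (length(bi) < 2) next
      fw <- cnn_forward(params, xs[bi, , drop = FALSE])
      gr <- cnn_backward(params, fw, yoh[bi, , drop = FALSE])
      t_step <- t_step + 1
      for (l in seq_along(params$conv)) {
        for (nm in c("W", "b")) {
          key <- paste0("c", l, nm)
          st <- adam_step(opt[[key]], params$conv[[l]][[nm]],
                          gr$conv[[l]][[paste0("d", nm)]], lr, t_step)
          params$conv[[l]][[nm]] <- st$param; opt[[key]] <- st$state
        }
      }
      for (nm in c("W1", "b1", "W2", "b2")) {
        st <- adam_step(opt[[nm]], params[[nm]], gr[[paste0("d", nm)]],
                        lr, t_step)
        params[[nm]] <- st$param; opt[[nm]] <- st$state
      }
    }
    if (!is.null(validation)) {
      vx <- sweep(sweep(as.matrix(validation$x), 2, center), 2, scale_, "/")
      vy <- factor(as.character(validation$y), levels = outcome_levels())
      voh <- cbind(vy == outcome_levels()[1], vy == outcome_levels()[2]) * 1
      vloss <- cnn_loss(cnn_forward(params, vx)$probs, voh)
      if (vloss < best$loss - 1e-5) {
        best <- list(loss = vloss, params = params, bad = 0L)
      } else {
        best$bad <- best$bad + 1L
        if (best$bad >= patience) { params <- best$params; break }
      }
    }
  }
  if (!is.null(validation) && is.finite(best$loss)) params <- best$params
  structure(list(params = params, center = center, scale = scale_,
                 levels = outcome_levels()), class = "cnn1d_model")
}

#' Class probabilities from a trained 1D CNN
#'
#' @param model A [train_cnn()] model.
#' @param x Feature matrix on the training feature space.
#' @return Matrix of per-row class probabilities (columns `pregnancy`,
#'   `non_pregnancy`), each row summing to 1.
#' @export
predict_cnn <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$center)) {
    stop("shape error: ", ncol(x), " features but the network was trained on ",
         length(model$center))
  }
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  p <- cnn_forward(model$params, xs)$probs
  colnames(p) <- model$levels
  p
}
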