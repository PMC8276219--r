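# Fully convolutional network for time-series classification: three 1-D
# convolution blocks (convolution -> batch normalization -> rectifier),
# global average pooling over time, and one fully connected softmax layer.
# Implemented natively: convolutions are im2col gathers followed by BLAS
# matrix products; training is mini-batch Adam on cross-entropy. All
# randomness flows through the R RNG, so runs are bit-reproducible.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# activations live as (batch * L) x C matrices, row r = (i - 1) * L + t.
# shift_index(): row indices into rbind(A, 0) realizing a temporal shift by
# `off`; out-of-range positions hit the appended zero row (zero padding).
shift_index <- function(b, L, off) {
  t_new <- seq_len(L) + off
  base <- ifelse(t_new >= 1 & t_new <= L, t_new, NA_integer_)
  idx <- rep(base, times = b) + rep((seq_len(b) - 1L) * L, each = L)
  idx[is.na(idx)] <- b * L + 1L
  idx
}

# im2col: (bL) x C input -> (bL) x (C*K) matrix; column (c-1)*K + k holds
# channel c shifted by offset k. Same padding: offsets center the kernel.
conv_offsets <- function(K) (seq_len(K) - 1L) - ((K - 1L) %/% 2L)

im2col <- function(A, b, L, K) {
  C <- ncol(A)
  A_pad <- rbind(A, 0)
  offs <- conv_offsets(K)
  idx_all <- unlist(lapply(offs, function(o) shift_index(b, L, o)))
  Xbig <- A_pad[idx_all, , drop = FALSE]          # (K*bL) x C, k blocks stacked
  # reshape to (bL) x (K*C): column (c-1)*K + k = block k of channel c
  matrix(Xbig, b * L, K * C)
}

col2im <- function(dXcol, b, L, K, C) {
  dA_pad <- matrix(0, b * L + 1L, C)
  offs <- conv_offsets(K)
  for (k in seq_len(K)) {
    idx <- shift_index(b, L, offs[k])
    cols <- (seq_len(C) - 1L) * K + k
    dA_pad[idx, ] <- dA_pad[idx, ] + dXcol[, cols, drop = FALSE]
  }
  dA_pad[seq_len(b * L), , drop = FALSE]
}

#' Build a fully convolutional network
#'
#' Three convolution blocks (1-D convolution with same padding -> batch
#' normalization -> ReLU) with the given widths and kernel sizes, global
#' average pooling over time, and one fully connected layer with softmax
#' outputs. Weight initialization is He-scaled and drawn from the R RNG.
#'
#' @param input_length Series length in samples; must be >= the largest
#'   kernel. Pooling removes the length dependence, so inference accepts any
#'   length >= the largest kernel.
#' @param n_channels Number of input channels.
#' @param n_classes Number of output classes.
#' @param widths Filter counts of the three blocks.
#' @param kernels Kernel sizes of the three blocks.
#' @param seed Integer seed for the weight draw.
#' @return An object of class `fcn_model`.
#' @export
build_fcn <- function(input_length, n_channels, n_classes,
                      widths = c(64, 128, 64), kernels = c(8, 5, 3),
                      seed = 1L) {
  stopifnot(length(widths) == length(kernels), all(widths >= 1),
            all(kernels >= 1), n_channels >= 1, n_classes >= 2)
  if (input_length < max(kernels)) {
    stop("invalid_dimensions: input_length must be >= largest kernel",
         call. = FALSE)
  }
  with_local_seed(seed, {
    c_in <- n_channels
    layers <- vector("list", length(widths))
    for (l in seq_along(widths)) {
      fan_in <- c_in * kernels[l]
      layers[[l]] <- list(
        W = matrix(rnorm(fan_in * widths[l], 0, sqrt(2 / fan_in)),
                   fan_in, widths[l]),
        gamma = rep(1, widths[l]), beta = rep(0, widths[l]),
        run_mean = rep(0, widths[l]), run_var = rep(1, widths[l]),
        K = kernels[l], C_in = c_in, C_out = widths[l])
      c_in <- widths[l]
    }
    structure(list(
      layers = layers,
      Wd = matrix(rnorm(c_in * n_classes, 0, sqrt(1 / c_in)), c_in, n_classes),
      bd = rep(0, n_classes),
      input_length = input_length, n_channels = n_channels,
      n_classes = n_classes, widths = widths, kernels = kernels,
      class_levels = NULL, history = NULL
    ), class = "fcn_model")
  })
}

#' Trainable parameter count of an FCN
#'
#' Convolution weights plus the batch-norm scale/shift pairs plus the dense
#' layer: `sum(C_in*K*C_out + 2*C_out) + C_last*n_classes + n_classes`.
#'
#' @param model An `fcn_model`.
#' @return Integer parameter count.
#' @export
fcn_param_count <- function(model) {
  stopifnot(inherits(model, "fcn_model"))
  conv <- sum(vapply(model$layers,
                     function(l) l$C_in * l$K * l$C_out + 2L * l$C_out, 0))
  as.integer(conv + nrow(model$Wd) * ncol(model$Wd) + length(model$bd))
}

# samples array (b x C x L) -> activation matrix (bL) x C
as_activation <- function(x) {
  b <- dim(x)[1]; C <- dim(x)[2]; L <- dim(x)[3]
  matrix(aperm(x, c(3, 1, 2)), b * L, C)
}

fcn_forward <- function(model, x, train = FALSE) {
  b <- dim(x)[1]; L <- dim(x)[3]
  A <- as_activation(x)
  cache <- list(b = b, L = L, blocks = vector("list", length(model$layers)))
  for (l in seq_along(model$layers)) {
    ly <- model$layers[[l]]
    Xcol <- im2col(A, b, L, ly$K)
    Z <- Xcol %*% ly$W
    if (train) {
      mu <- colMeans(Z)
      va <- colMeans(Z^2) - mu^2
      model$layers[[l]]$run_mean <- BN_MOMENTUM * ly$run_mean +
        (1 - BN_MOMENTUM) * mu
      model$layers[[l]]$run_var <- BN_MOMENTUM * ly$run_var +
        (1 - BN_MOMENTUM) * va
    } else {
      mu <- ly$run_mean
      va <- ly$run_var
    }
    inv_sd <- 1 / sqrt(va + BN_EPS)
    Zhat <- sweep(sweep(Z, 2, mu, "-"), 2, inv_sd, "*")
    Y <- sweep(sweep(Zhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    H <- Y * (Y > 0)
    cache$blocks[[l]] <- list(Xcol = Xcol, Zhat = Zhat, inv_sd = inv_sd,
                              mask = Y > 0)
    A <- H
  }
  group <- rep(seq_len(b), each = L)
  G <- rowsum(A, group) / L
  logits <- sweep(G %*% model$Wd, 2, model$bd, "+")
  logits <- logits - apply(logits, 1, max)
  P <- exp(logits)
  P <- P / rowSums(P)
  list(P = P, G = G, cache = cache, model = model)
}

fcn_backward <- function(model, fwd, y_onehot) {
  b <- fwd$cache$b; L <- fwd$cache$L
  grads <- list(layers = vector("list", length(model$layers)))
  dlogits <- (fwd$P - y_onehot) / b
  grads$Wd <- crossprod(fwd$G, dlogits)
  grads$bd <- colSums(dlogits)
  dG <- dlogits %*% t(model$Wd)
  dA <- dG[rep(seq_len(b), each = L), , drop = FALSE] / L
  for (l in rev(seq_along(model$layers))) {
    ly <- model$layers[[l]]
    blk <- fwd$cache$blocks[[l]]
    dY <- dA * blk$mask
    grads$layers[[l]] <- list(gamma = colSums(dY * blk$Zhat),
                              beta = colSums(dY))
    dZhat <- sweep(dY, 2, ly$gamma, "*")
    N <- nrow(dZhat)
    s1 <- colSums(dZhat)
    s2 <- colSums(dZhat * blk$Zhat)
    dZ <- sweep(dZhat, 2, s1 / N, "-") -
      sweep(blk$Zhat, 2, s2 / N, "*")
    dZ <- sweep(dZ, 2, blk$inv_sd, "*")
    grads$layers[[l]]$W <- crossprod(blk$Xcol, dZ)
    if (l > 1) {
      dXcol <- dZ %*% t(ly$W)
      dA <- col2im(dXcol, b, L, ly$K, ly$C_in)
    }
  }
  grads
}

adam_init <- function(model) {
  zero_like <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
                           else rep(0, length(p))
  list(
    layers = lapply(model$layers, function(ly) {
      list(W = list(m = zero_like(ly$W), v = zero_like(ly$W)),
           gamma = list(m = zero_like(ly$gamma), v = zero_like(ly$gamma)),
           beta = list(m = zero_like(ly$beta), v = zero_like(ly$beta)))
    }),
    Wd = list(m = zero_like(model$Wd), v = zero_like(model$Wd)),
    bd = list(m = zero_like(model$bd), v = zero_like(model$bd)),
    t = 0L)
}

adam_step <- function(p, g, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8, t) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

#' Train an FCN by mini-batch gradient descent on cross-entropy
#'
#' Adam updates over shuffled mini-batches; every random draw (shuffling)
#' comes from the seed, so the final weights and loss are deterministic.
#'
#' @param model An `fcn_model` from [build_fcn()].
#' @param x Sample array (n x channels x length).
#' @param labels Factor of labels (>= 2 classes present).
#' @param epochs Number of passes over the data.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed for shuffling.
#' @return The trained `fcn_model`, with `$history` holding the per-epoch
#'   mean training loss and `$class_levels` the label levels.
#' @export
train_fcn <- function(model, x, labels, epochs = 20, learning_rate = 1e-3,
                      batch_size = 32, seed = 1L) {
  stopifnot(inherits(model, "fcn_model"), length(dim(x)) == 3,
            dim(x)[1] == length(labels))
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop("single_class_training: need >= 2 classes", call. = FALSE)
  }
  n <- dim(x)[1]
  y <- diag(model$n_classes)[as.integer(labels), , drop = FALSE]
  opt <- adam_init(model)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_local_seed(derive_seed(seed, 5000L + ep), sample.int(n))
    losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      fwd <- fcn_forward(model, x[idx, , , drop = FALSE], train = TRUE)
      model <- fwd$model                       # running BN stats
      pt <- rowSums(fwd$P * y[idx, , drop = FALSE])
      loss <- -mean(log(pmax(pt, 1e-12)))
      if (!is.finite(loss)) {
        stop("divergence: non-finite training loss", call. = FALSE)
      }
      losses <- c(losses, loss)
      g <- fcn_backward(model, fwd, y[idx, , drop = FALSE])
      opt$t <- opt$t + 1L
      for (l in seq_along(model$layers)) {
        for (p in c("W", "gamma", "beta")) {
          up <- adam_step(model$layers[[l]][[p]], g$layers[[l]][[p]],
                          opt$layers[[l]][[p]], learning_rate, t = opt$t)
          model$layers[[l]][[p]] <- up$p
          opt$layers[[l]][[p]] <- up$st
        }
      }
      up <- adam_step(model$Wd, g$Wd, opt$Wd, learning_rate, t = opt$t)
      model$Wd <- up$p; opt$Wd <- up$st
      up <- adam_step(model$bd, g$bd, opt$bd, learning_rate, t = opt$t)
      model$bd <- up$p; opt$bd <- up$st
    }
    history[ep] <- mean(losses)
  }
  model$history <- history
  model$class_levels <- levels(labels)
  model
}

#' Class probabilities and labels from a trained FCN
#'
#' @param model A trained `fcn_model`.
#' @param x Sample array (n x channels x length).
#' @param batch_size Samples per forward batch.
#' @return List with `prob` (n x n_classes matrix, rows summing to 1) and
#'   `label` (factor, when the model has been trained on labeled data).
#' @export
fcn_predict <- function(model, x, batch_size = 64) {
  stopifnot(inherits(model, "fcn_model"), length(dim(x)) == 3)
  n <- dim(x)[1]
  prob <- matrix(NA_real_, n, model$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    prob[idx, ] <- fcn_forward(model, x[idx, , , drop = FALSE],
                               train = FALSE)$P
  }
  lab <- if (!is.null(model$class_levels)) {
    factor(model$class_levels[apply(prob, 1, which.max)],
           levels = model$class_levels)
  }
  list(prob = prob, label = lab)
}
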