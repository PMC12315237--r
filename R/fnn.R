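# Multi-task feedforward network trained with plain matrix algebra:
# LeakyReLU hidden layers with inverted dropout, a 5-unit output head
# (softmax over CN/MCI/DEM + two linear regression units), masked
# cross-entropy + MAE loss with equal weighting, SGD with momentum and an
# exponentially decaying learning rate.

#' Neural-network hyperparameter configuration
#'
#' Defaults sit inside the documented search ranges (hidden layers 2-5,
#' hidden size 128-512, dropout 0-0.5, LeakyReLU slope 0.01-0.1, L2 weight
#' 1e-7 to 1e-4, momentum 0-0.9, learning rate 1e-5 to 1e-1, LR decay gamma
#' 0.1-0.9).
#'
#' @param n_hidden_layers,hidden_size Architecture.
#' @param dropout Dropout rate after each activation.
#' @param leaky_slope Negative-side slope of the LeakyReLU.
#' @param l2_weight L2 weight-decay coefficient.
#' @param momentum SGD momentum.
#' @param learning_rate Initial learning rate.
#' @param lr_gamma Per-epoch multiplicative learning-rate decay.
#' @param epochs,batch_size Training length and batch size.
#' @param seed Seed for weight init and batch shuffling.
#' @return An `l2c_fnn_config` list.
#' @export
fnn_config <- function(n_hidden_layers = 2, hidden_size = 128, dropout = 0.1,
                       leaky_slope = 0.05, l2_weight = 1e-5, momentum = 0.9,
                       learning_rate = 0.02, lr_gamma = 0.9, epochs = 60,
                       batch_size = 128, seed = 1) {
  cfg <- list(n_hidden_layers = n_hidden_layers, hidden_size = hidden_size,
              dropout = dropout, leaky_slope = leaky_slope,
              l2_weight = l2_weight, momentum = momentum,
              learning_rate = learning_rate, lr_gamma = lr_gamma,
              epochs = epochs, batch_size = batch_size, seed = seed)
  with(cfg, stopifnot(
    n_hidden_layers >= 2, n_hidden_layers <= 5,
    hidden_size >= 128, hidden_size <= 512,
    dropout >= 0, dropout <= 0.5,
    leaky_slope >= 0.01, leaky_slope <= 0.1,
    l2_weight >= 1e-7, l2_weight <= 1e-4,
    momentum >= 0, momentum <= 0.9,
    learning_rate >= 1e-5, learning_rate <= 1e-1,
    lr_gamma >= 0.1, lr_gamma <= 0.9,
    epochs >= 1, batch_size >= 1))
  structure(cfg, class = "l2c_fnn_config")
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

init_fnn_weights <- function(d_in, config) {
  sizes <- c(d_in, rep(config$hidden_size, config$n_hidden_layers), 5L)
  lapply(seq_len(length(sizes) - 1), function(l) {
    list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                 sd = sqrt(2 / sizes[l])),
                    nrow = sizes[l]),
         b = rep(0, sizes[l + 1]))
  })
}

fnn_forward <- function(weights, X, config, dropout_masks = NULL) {
  n_layers <- length(weights)
  acts <- list(X)
  pre <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    z <- sweep(acts[[l]] %*% weights[[l]]$W, 2, weights[[l]]$b, "+")
    pre[[l]] <- z
    if (l < n_layers) {
      a <- leaky_relu(z, config$leaky_slope)
      if (!is.null(dropout_masks)) a <- a * dropout_masks[[l]]
      acts[[l + 1]] <- a
    } else {
      acts[[l + 1]] <- z
    }
  }
  list(acts = acts, pre = pre, out = acts[[n_layers + 1]])
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Masked multi-task loss and output-layer gradient.
# dx_idx: 1..3 or NA; y_mmse / y_vent on the Gauss-rank scale or NA.
fnn_loss_grad <- function(out, dx_idx, y_mmse, y_vent) {
  n <- nrow(out)
  grad <- matrix(0, n, 5)
  loss <- 0
  has_dx <- !is.na(dx_idx)
  if (any(has_dx)) {
    p <- softmax_rows(out[has_dx, 1:3, drop = FALSE])
    ce_idx <- cbind(seq_len(sum(has_dx)), dx_idx[has_dx])
    loss <- loss + sum(-log(pmax(p[ce_idx], 1e-12)))
    g <- p
    g[ce_idx] <- g[ce_idx] - 1
    grad[has_dx, 1:3] <- g
  }
  for (task in list(list(col = 4L, y = y_mmse), list(col = 5L, y = y_vent))) {
    has <- !is.na(task$y)
    if (any(has)) {
      err <- out[has, task$col] - task$y[has]
      loss <- loss + sum(abs(err))
      grad[has, task$col] <- sign(err)
    }
  }
  list(loss = loss / n, grad = grad / n)
}

#' Train the multi-task feedforward network
#'
#' @param X Numeric design matrix (preprocessed features).
#' @param dx_idx Integer class index 1..3 (CN, MCI, DEM) or `NA` per row.
#' @param y_mmse,y_vent Gauss-rank-scale regression targets or `NA` per row.
#' @param config An [fnn_config()].
#' @return An `l2c_fnn` fit (weights, config, loss trace).
#' @export
train_fnn <- function(X, dx_idx, y_mmse, y_vent, config = fnn_config()) {
  if (all(is.na(dx_idx)) && all(is.na(y_mmse)) && all(is.na(y_vent))) {
    stop("no sample with any observed target")
  }
  set.seed(config$seed)
  n <- nrow(X)
  weights <- init_fnn_weights(ncol(X), config)
  velocity <- lapply(weights, function(w)
    list(W = matrix(0, nrow(w$W), ncol(w$W)), b = rep(0, length(w$b))))
  n_layers <- length(weights)
  epoch_losses <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate * config$lr_gamma^(epoch - 1)
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    total <- 0
    for (idx in batches) {
      Xb <- X[idx, , drop = FALSE]
      masks <- NULL
      if (config$dropout > 0) {
        masks <- lapply(seq_len(n_layers - 1), function(l)
          matrix(stats::rbinom(length(idx) * config$hidden_size, 1,
                               1 - config$dropout) / (1 - config$dropout),
                 nrow = length(idx)))
      }
      fw <- fnn_forward(weights, Xb, config, masks)
      lg <- fnn_loss_grad(fw$out, dx_idx[idx], y_mmse[idx], y_vent[idx])
      total <- total + lg$loss * length(idx)

      delta <- lg$grad
      for (l in rev(seq_len(n_layers))) {
        gW <- crossprod(fw$acts[[l]], delta) + config$l2_weight * weights[[l]]$W
        gb <- colSums(delta)
        if (l > 1) {
          back <- delta %*% t(weights[[l]]$W)
          dmask <- leaky_relu_grad(fw$pre[[l - 1]], config$leaky_slope)
          if (!is.null(masks)) dmask <- dmask * masks[[l - 1]]
          delta <- back * dmask
        }
        velocity[[l]]$W <- config$momentum * velocity[[l]]$W - lr * gW
        velocity[[l]]$b <- config$momentum * velocity[[l]]$b - lr * gb
        weights[[l]]$W <- weights[[l]]$W + velocity[[l]]$W
        weights[[l]]$b <- weights[[l]]$b + velocity[[l]]$b
      }
    }
    epoch_losses[epoch] <- total / n
  }
  structure(list(weights = weights, config = config,
                 epoch_losses = epoch_losses, d_in = ncol(X)),
            class = "l2c_fnn")
}

#' Raw network outputs (softmax probabilities + Gauss-rank-scale regressions)
#'
#' @param fit An `l2c_fnn` fit.
#' @param X Design matrix with the training layout.
#' @return Matrix with columns `p_cn`, `p_mci`, `p_dem`, `mmse_gr`, `vent_gr`.
#' @export
predict_fnn_raw <- function(fit, X) {
  if (ncol(X) != fit$d_in) stop("feature arity mismatch with trained network")
  out <- fnn_forward(fit$weights, X, fit$config)$out
  probs <- softmax_rows(out[, 1:3, drop = FALSE])
  res <- cbind(probs, out[, 4:5, drop = FALSE])
  colnames(res) <- c("p_cn", "p_mci", "p_dem", "mmse_gr", "vent_gr")
  res
}
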