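#' Network architecture specifications
#'
#' Two fixed architectures are used as ensemble members. The convolutional
#' variant has two 1-D valid convolutions (kernel 8 with 64 filters, then
#' kernel 64 with 16 filters, both with rectifier activations), a flatten
#' step, dropout at rate 0.75, a fully connected layer of 128 rectifier units
#' and a linear output. The dense variant stacks layers of 120 (sigmoid), 60
#' (rectifier), dropout at rate 0.20, 15 (rectifier) and a linear output.
#' Both produce a single regression output.
#'
#' @return An `architecture_spec` list.
#' @export
architecture_conv <- function() {
  structure(list(variant = "conv",
                 conv = list(list(kernel = 8L, filters = 64L),
                             list(kernel = 64L, filters = 16L)),
                 dropout = 0.75, dense_units = 128L),
            class = "architecture_spec")
}

#' @rdname architecture_conv
#' @export
architecture_dense <- function() {
  structure(list(variant = "dense",
                 units = c(120L, 60L, 15L),
                 activations = c("sigmoid", "relu", "relu"),
                 dropout_after = 2L, dropout = 0.20),
            class = "architecture_spec")
}

#' Training configuration for ensemble members
#'
#' Loss is mean squared error on scaled targets, optimized with Adam.
#' Validation root-mean-square error is monitored each epoch: training halts
#' when it has not improved for `patience_stop` epochs (the best-epoch
#' weights are restored) and the learning rate is multiplied by `lr_factor`
#' after `patience_lr` stagnant epochs, down to `lr_min`. The three member
#' initialization seeds are fixed at 7, 14 and 21. The initial learning rate,
#' batch size, epoch cap and schedule constants are package defaults (the
#' design source does not state them) and are all configurable; `max_epochs`
#' may be a scalar or a named vector with per-variant caps, e.g.
#' `c(conv = 4, dense = 60)` for reduced-budget runs.
#'
#' @param seeds Member initialization seeds.
#' @param patience_stop Early-stopping patience in epochs.
#' @param patience_lr Learning-rate-reduction patience (must be smaller).
#' @param lr_factor Multiplicative learning-rate reduction factor.
#' @param lr_init Initial Adam learning rate.
#' @param lr_min Learning-rate floor.
#' @param max_epochs Epoch cap (scalar or named per-variant vector).
#' @param batch_size Minibatch size.
#' @return A `train_config` list.
#' @export
train_config <- function(seeds = c(7L, 14L, 21L), patience_stop = 25L,
                         patience_lr = 20L, lr_factor = 0.5,
                         lr_init = 1e-3, lr_min = 1e-5,
                         max_epochs = 500L, batch_size = 32L) {
  if (patience_lr >= patience_stop) {
    stop("patience_lr must be smaller than patience_stop", call. = FALSE)
  }
  structure(list(seeds = as.integer(seeds),
                 patience_stop = as.integer(patience_stop),
                 patience_lr = as.integer(patience_lr),
                 lr_factor = lr_factor, lr_init = lr_init, lr_min = lr_min,
                 max_epochs = max_epochs,
                 batch_size = as.integer(batch_size)),
            class = "train_config")
}

epoch_cap <- function(config, variant) {
  me <- config$max_epochs
  if (!is.null(names(me)) && variant %in% names(me)) {
    as.integer(me[[variant]])
  } else {
    as.integer(me[[1L]])
  }
}

glorot <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

#' Build an untrained network
#'
#' Weights are initialized deterministically from `seed` (Glorot uniform,
#' zero biases), so the same seed always produces identical initial weights.
#'
#' @param spec An [architecture_conv()] or [architecture_dense()] spec.
#' @param input_length Number of spectral features. The convolutional variant
#'   requires more than 71 features so both valid convolutions leave at least
#'   one output position.
#' @param seed Initialization seed.
#' @return An object of class `nn_model`.
#' @export
build_model <- function(spec, input_length, seed) {
  stopifnot(inherits(spec, "architecture_spec"))
  set.seed(seed)
  layers <- list()
  if (spec$variant == "conv") {
    if (input_length <= 71L) {
      stop("conv variant requires input length > 71 (got ", input_length, ")",
           call. = FALSE)
    }
    len <- input_length
    chans <- 1L
    for (cv in spec$conv) {
      k <- cv$kernel
      f <- cv$filters
      layers[[length(layers) + 1L]] <- list(
        type = "conv", kernel = k, channels = chans, filters = f,
        W = array(glorot(k * chans * f, k * chans, k * f), c(chans, f, k)),
        b = rep(0, f), act = "relu")
      len <- len - k + 1L
      chans <- f
    }
    flat <- len * chans
    layers[[length(layers) + 1L]] <- list(type = "flatten")
    layers[[length(layers) + 1L]] <- list(type = "dropout", p = spec$dropout)
    layers[[length(layers) + 1L]] <- list(
      type = "dense", W = matrix(glorot(flat * spec$dense_units, flat,
                                        spec$dense_units),
                                 flat, spec$dense_units),
      b = rep(0, spec$dense_units), act = "relu")
    layers[[length(layers) + 1L]] <- list(
      type = "dense", W = matrix(glorot(spec$dense_units, spec$dense_units,
                                        1L), spec$dense_units, 1L),
      b = 0, act = "linear")
  } else {
    widths <- c(input_length, spec$units)
    for (i in seq_along(spec$units)) {
      layers[[length(layers) + 1L]] <- list(
        type = "dense",
        W = matrix(glorot(widths[i] * widths[i + 1L], widths[i],
                          widths[i + 1L]), widths[i], widths[i + 1L]),
        b = rep(0, widths[i + 1L]), act = spec$activations[i])
      if (i == spec$dropout_after) {
        layers[[length(layers) + 1L]] <- list(type = "dropout",
                                              p = spec$dropout)
      }
    }
    layers[[length(layers) + 1L]] <- list(
      type = "dense",
      W = matrix(glorot(spec$units[length(spec$units)],
                        spec$units[length(spec$units)], 1L),
                 spec$units[length(spec$units)], 1L),
      b = 0, act = "linear")
  }
  structure(list(variant = spec$variant, input_length = as.integer(input_length),
                 seed = as.integer(seed), layers = layers),
            class = "nn_model")
}

#' Number of trainable parameters
#' @param model An `nn_model`.
#' @return Integer count of weights and biases.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l) {
    if (is.null(l$W)) 0L else length(l$W) + length(l$b)
  }, integer(1L)))
}

activate <- function(x, act) {
  switch(act,
         relu = pmax(x, 0),
         sigmoid = 1 / (1 + exp(-x)),
         linear = x)
}

activate_grad <- function(a, act) {
  # gradient expressed through the activation output a
  switch(act,
         relu = (a > 0) * 1,
         sigmoid = a * (1 - a),
         linear = 1)
}

# forward pass; X is an n x p matrix. Returns list(out, cache) where cache
# holds per-layer inputs/outputs needed by the backward pass. Dropout is
# inverted (scaled at train time) and only active when training = TRUE.
nn_forward <- function(model, x, training = FALSE) {
  n <- nrow(x)
  cache <- vector("list", length(model$layers))
  if (model$variant == "conv") {
    # channels-first batch layout: (channels, length, samples)
    cur <- array(t(x), dim = c(1L, ncol(x), n))
  } else {
    cur <- x
  }
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      pre <- .conv1d_forward(cur, l$W, l$b)
      out <- activate(pre, l$act)
      cache[[i]] <- list(input = cur, out = out)
      cur <- out
    } else if (l$type == "flatten") {
      dims <- dim(cur)
      cache[[i]] <- list(dims = dims)
      cur <- t(matrix(cur, nrow = dims[1L] * dims[2L]))
    } else if (l$type == "dropout") {
      if (training && l$p > 0) {
        mask <- matrix(stats::runif(length(cur)) >= l$p,
                       nrow(cur), ncol(cur)) / (1 - l$p)
        cur <- cur * mask
        cache[[i]] <- list(mask = mask)
      }
    } else if (l$type == "dense") {
      pre <- sweep(cur %*% l$W, 2L, l$b, `+`)
      out <- activate(pre, l$act)
      cache[[i]] <- list(input = cur, out = out)
      cur <- out
    }
  }
  list(out = cur, cache = cache)
}

# backward pass for mean-squared-error gradients; returns a list of
# per-layer gradients (NULL for parameterless layers)
nn_backward <- function(model, cache, d_out) {
  grads <- vector("list", length(model$layers))
  cur <- d_out
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    if (l$type == "dense") {
      cur <- cur * activate_grad(cache[[i]]$out, l$act)
      grads[[i]] <- list(dW = crossprod(cache[[i]]$input, cur),
                         db = colSums(cur))
      cur <- cur %*% t(l$W)
    } else if (l$type == "dropout") {
      if (!is.null(cache[[i]]$mask)) cur <- cur * cache[[i]]$mask
    } else if (l$type == "flatten") {
      dims <- cache[[i]]$dims
      cur <- array(t(cur), dim = dims)
    } else if (l$type == "conv") {
      cur <- cur * activate_grad(cache[[i]]$out, l$act)
      need_dx <- i > 1L
      bw <- .conv1d_backward(cache[[i]]$input, l$W, cur, need_dx)
      grads[[i]] <- list(dW = bw$dW, db = bw$db)
      if (need_dx) cur <- bw$dX
    }
  }
  grads
}

#' Predict with a trained network
#'
#' @param model An `nn_model`.
#' @param x Feature matrix (rows = spectra), already standardized.
#' @param batch Chunk size for memory-bounded evaluation.
#' @return Numeric vector of (scaled-space) predictions.
#' @export
nn_predict <- function(model, x, batch = 128L) {
  x <- as.matrix(x)
  if (ncol(x) != model$input_length) {
    stop("feature count does not match the model input length", call. = FALSE)
  }
  out <- numeric(nrow(x))
  starts <- seq(1L, nrow(x), by = batch)
  for (s in starts) {
    idx <- s:min(s + batch - 1L, nrow(x))
    out[idx] <- drop(nn_forward(model, x[idx, , drop = FALSE])$out)
  }
  out
}

adam_init <- function(model) {
  lapply(model$layers, function(l) {
    if (is.null(l$W)) return(NULL)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_update <- function(model, state, grads, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    st <- state[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$dW
    st$vW <- beta2 * st$vW + (1 - beta2) * g$dW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$db
    st$vb <- beta2 * st$vb + (1 - beta2) * g$db^2
    model$layers[[i]]$W <- model$layers[[i]]$W -
      lr * (st$mW / bc1) / (sqrt(st$vW / bc2) + eps)
    model$layers[[i]]$b <- model$layers[[i]]$b -
      lr * (st$mb / bc1) / (sqrt(st$vb / bc2) + eps)
    state[[i]] <- st
  }
  list(model = model, state = state)
}

extract_weights <- function(model) {
  lapply(model$layers, function(l) if (is.null(l$W)) NULL else
    list(W = l$W, b = l$b))
}

restore_weights <- function(model, weights) {
  for (i in seq_along(weights)) {
    if (!is.null(weights[[i]])) {
      model$layers[[i]]$W <- weights[[i]]$W
      model$layers[[i]]$b <- weights[[i]]$b
    }
  }
  model
}

#' Train one ensemble member
#'
#' Minimizes mean squared error with Adam on minibatches. After each epoch
#' the validation RMSE is evaluated; the best-epoch weights are kept and
#' restored when training stops (epoch cap or early stopping). All data are
#' expected in scaled space (standardized features, range-scaled targets).
#'
#' @param model An `nn_model` (freshly built; its seed determines shuffling
#'   and dropout as well).
#' @param x_cal,y_cal Calibration features and scaled targets.
#' @param x_val,y_val Validation features and scaled targets (animal-level
#'   disjoint from calibration).
#' @param config A [train_config()].
#' @return The trained model, with a `history` attribute (data.frame of
#'   epoch, training loss, validation RMSE and learning rate).
#' @export
train_member <- function(model, x_cal, y_cal, x_val, y_val,
                         config = train_config()) {
  set.seed(model$seed + 1000L)   # training-time stream (shuffle, dropout)
  n <- nrow(x_cal)
  lr <- config$lr_init
  state <- adam_init(model)
  step <- 0L
  best_val <- Inf
  best_weights <- extract_weights(model)
  best_epoch <- 0L
  wait_stop <- 0L
  wait_lr <- 0L
  cap <- epoch_cap(config, model$variant)
  hist <- vector("list", cap)
  for (epoch in seq_len(cap)) {
    idx <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (s in seq(1L, n, by = config$batch_size)) {
      bi <- idx[s:min(s + config$batch_size - 1L, n)]
      fw <- nn_forward(model, x_cal[bi, , drop = FALSE], training = TRUE)
      resid <- drop(fw$out) - y_cal[bi]
      loss <- mean(resid^2)
      if (!is.finite(loss)) {
        stop(sprintf("training diverged (member %s/seed %d, epoch %d)",
                     model$variant, model$seed, epoch), call. = FALSE)
      }
      grads <- nn_backward(model, fw$cache,
                           matrix(2 * resid / length(bi), ncol = 1L))
      step <- step + 1L
      upd <- adam_update(model, state, grads, lr, step)
      model <- upd$model
      state <- upd$state
      ep_loss <- ep_loss + loss
      nb <- nb + 1L
    }
    val_rmse <- sqrt(mean((nn_predict(model, x_val) - y_val)^2))
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                val_rmse = val_rmse, lr = lr)
    if (val_rmse < best_val - 1e-12) {
      best_val <- val_rmse
      best_weights <- extract_weights(model)
      best_epoch <- epoch
      wait_stop <- 0L
      wait_lr <- 0L
    } else {
      wait_stop <- wait_stop + 1L
      wait_lr <- wait_lr + 1L
      if (wait_lr >= config$patience_lr && lr > config$lr_min) {
        lr <- max(lr * config$lr_factor, config$lr_min)
        wait_lr <- 0L
      }
      if (wait_stop >= config$patience_stop) break
    }
  }
  model <- restore_weights(model, best_weights)
  attr(model, "history") <- do.call(rbind, hist[!vapply(hist, is.null,
                                                        logical(1L))])
  attr(model, "best_epoch") <- best_epoch
  attr(model, "best_val_rmse") <- best_val
  model
}
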