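# Epoch-level 2D convolutional network on time-frequency tensors.
#
# Architecture (fixed): conv(16, 3x5) -> ReLU -> batch norm -> max pool 2x2
# -> dropout(0.4) -> conv(32, 3x5) -> ReLU -> batch norm -> max pool 2x2 ->
# dropout(0.4) -> flatten -> dense(1, sigmoid). Binary cross-entropy loss,
# Adam optimizer. Convolutions are valid (no padding).
#
# Activations live in (H*W*N) x channels matrices, rows ordered height
# fastest, then width, then batch sample; convolution is im2col + one BLAS
# matrix product (C++ helpers do the data movement).

#' CNN specification
#'
#' @param filters1,filters2 filter counts of the two convolutional blocks.
#' @param kernel kernel size `(rows, cols)` = (frequencies, time points).
#' @param dropout_rate dropout probability after each pooling stage.
#' @param learning_rate,batch_size Adam learning rate and minibatch size.
#' @param max_train_epochs maximum training passes over the data.
#' @param early_stop `"internal_val"` (monitor a validation split carved from
#'   the training subjects; leakage-safe default),
#'   `"paper_faithful_test_monitor"` (monitor the held-out test epochs — this
#'   leaks the test subject into the stopping decision and is provided only
#'   to mirror protocols that stop on the test fold), or `"none"`.
#' @param patience early-stopping patience (passes without validation
#'   improvement); the best weights are restored.
#' @param min_train_epochs burn-in: the patience counter only starts after
#'   this many passes (the best-weights tracking always runs).
#' @param val_frac fraction of training epochs carved out for monitoring when
#'   no explicit validation set is supplied.
#' @param activation_before_bn if `TRUE` (default) the block order is
#'   conv -> ReLU -> batch norm; `FALSE` swaps to the conventional
#'   conv -> batch norm -> ReLU.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(filters1 = 16, filters2 = 32, kernel = c(3, 5),
                     dropout_rate = 0.4, learning_rate = 0.001,
                     batch_size = 32, max_train_epochs = 50,
                     early_stop = c("internal_val",
                                    "paper_faithful_test_monitor", "none"),
                     patience = 5, min_train_epochs = 1, val_frac = 0.15,
                     activation_before_bn = TRUE, seed = 1) {
  early_stop <- match.arg(early_stop)
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("need 0 <= dropout_rate < 1")
  spec <- list(filters1 = as.integer(filters1), filters2 = as.integer(filters2),
               kernel = as.integer(kernel), pool = c(2L, 2L),
               dropout_rate = dropout_rate, learning_rate = learning_rate,
               batch_size = as.integer(batch_size),
               max_train_epochs = as.integer(max_train_epochs),
               early_stop = early_stop, patience = as.integer(patience),
               min_train_epochs = as.integer(min_train_epochs),
               val_frac = val_frac,
               activation_before_bn = isTRUE(activation_before_bn),
               seed = as.integer(seed))
  class(spec) <- "cnn_spec"
  spec
}

#' @noRd
cnn_dims <- function(input_dim, spec) {
  H <- input_dim[1]; W <- input_dim[2]; C <- input_dim[3]
  kh <- spec$kernel[1]; kw <- spec$kernel[2]
  H1 <- H - kh + 1; W1 <- W - kw + 1
  H2 <- H1 %/% 2; W2 <- W1 %/% 2
  H3 <- H2 - kh + 1; W3 <- W2 - kw + 1
  H4 <- H3 %/% 2; W4 <- W3 %/% 2
  if (H1 < 1 || W1 < 1 || H2 < kh || W2 < kw || H4 < 1 || W4 < 1) {
    stopf(paste0("input (%d, %d, %d) too small for two conv(%dx%d)+pool ",
                 "blocks; minimum input is (%d, %d, channels)"),
          H, W, C, kh, kw, 3 * kh + 1, 3 * kw + 1)
  }
  list(H = H, W = W, C = C, H1 = H1, W1 = W1, H2 = H2, W2 = W2,
       H3 = H3, W3 = W3, H4 = H4, W4 = W4,
       D_out = H4 * W4 * spec$filters2)
}

#' Build an (untrained) epoch-level CNN
#'
#' Validates that `input_dim` admits two valid-convolution + pooling blocks,
#' initializes the parameters, and attaches a structural introspection
#' report.
#'
#' @param input_dim `(n_freqs, n_times, n_channels)` of one epoch tensor.
#' @param spec a [cnn_spec()].
#' @return An object of class `eeg_cnn`; `cnn_architecture()` returns its
#'   layer report.
#' @export
build_cnn <- function(input_dim, spec = cnn_spec()) {
  input_dim <- as.integer(input_dim)
  d <- cnn_dims(input_dim, spec)
  model <- structure(list(spec = spec, input_dim = input_dim, dims = d,
                          params = NULL, running = NULL, trained = FALSE,
                          history = NULL),
                     class = "eeg_cnn")
  model$params <- with_seed(spec$seed, cnn_init_params(model))
  model$running <- cnn_init_running(spec)
  model
}

#' @noRd
cnn_init_params <- function(model) {
  s <- model$spec; d <- model$dims
  kh <- s$kernel[1]; kw <- s$kernel[2]
  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  list(
    W1 = glorot(kh * kw * d$C, s$filters1, kh * kw * d$C, kh * kw * s$filters1),
    b1 = numeric(s$filters1),
    g1 = rep(1, s$filters1), be1 = numeric(s$filters1),
    W2 = glorot(kh * kw * s$filters1, s$filters2, kh * kw * s$filters1,
                kh * kw * s$filters2),
    b2 = numeric(s$filters2),
    g2 = rep(1, s$filters2), be2 = numeric(s$filters2),
    Wd = glorot(d$D_out, 1L, d$D_out, 1L),
    bd = 0
  )
}

#' @noRd
cnn_init_running <- function(spec) {
  list(m1 = numeric(spec$filters1), v1 = rep(1, spec$filters1),
       m2 = numeric(spec$filters2), v2 = rep(1, spec$filters2))
}

#' Structural introspection report
#'
#' @param model an `eeg_cnn`.
#' @return Data frame listing each layer's kind, configuration and output
#'   shape, in forward order.
#' @export
cnn_architecture <- function(model) {
  stopifnot(inherits(model, "eeg_cnn"))
  s <- model$spec; d <- model$dims
  shp <- function(...) paste(c(...), collapse = " x ")
  conv_block <- function(i, f, Hc, Wc, Hp, Wp) {
    kinds <- c("conv2d", "activation_relu", "batch_norm")
    if (!s$activation_before_bn) kinds <- c("conv2d", "batch_norm", "activation_relu")
    data.frame(
      kind = c(kinds, "max_pool2d", "dropout"),
      config = c(sprintf("%d filters, (%d, %d) kernel, valid", f,
                         s$kernel[1], s$kernel[2]),
                 "", "", "(2, 2)", sprintf("rate %.2f", s$dropout_rate)),
      output_shape = c(rep(shp(Hc, Wc, f), 3), rep(shp(Hp, Wp, f), 2)),
      stringsAsFactors = FALSE)
  }
  rbind(
    conv_block(1, s$filters1, d$H1, d$W1, d$H2, d$W2),
    conv_block(2, s$filters2, d$H3, d$W3, d$H4, d$W4),
    data.frame(kind = c("flatten", "dense"),
               config = c("", "1 unit, sigmoid"),
               output_shape = c(as.character(d$D_out), "1"),
               stringsAsFactors = FALSE)
  )
}

# ---- forward / backward ---------------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

#' @noRd
bn_forward <- function(X, gamma, beta, run_m, run_v, training) {
  if (training) {
    mom <- col_moments(X)
    mu <- mom$mean
    v <- pmax(mom$meansq - mu^2, 0)
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- col_affine(X, invstd, -mu * invstd)
    list(out = col_affine(xhat, gamma, beta), xhat = xhat,
         invstd = invstd, mu = mu, v = v)
  } else {
    invstd <- 1 / sqrt(run_v + BN_EPS)
    list(out = col_affine(X, gamma * invstd, beta - run_m * gamma * invstd))
  }
}

#' @noRd
bn_backward <- function(dout, cache, gamma) {
  m <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- col_affine(dout, gamma, numeric(length(gamma)))
  s1m <- colSums(dxhat) / m
  s2m <- colSums(dxhat * cache$xhat) / m
  dx <- bn_backward_core(dxhat, cache$xhat, s1m, s2m, cache$invstd)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Lay a flattened (N x D) feature matrix out as the (H*W*N) x C activation
# format the convolution kernels expect.
#' @noRd
cnn_layout <- function(X, d) {
  arr <- array(t(X), c(d$H, d$W, d$C, nrow(X)))
  A <- aperm(arr, c(1, 2, 4, 3))
  dim(A) <- c(d$H * d$W * nrow(X), d$C)
  A
}

# Forward pass over the samples `idx` of a pre-laid-out activation matrix.
#' @noRd
cnn_forward_laid <- function(model, Afull, n_all, idx, training = FALSE,
                             params = model$params,
                             running = model$running) {
  s <- model$spec; d <- model$dims
  Nb <- length(idx)
  kh <- s$kernel[1]; kw <- s$kernel[2]
  ones1 <- rep(1, s$filters1); ones2 <- rep(1, s$filters2)

  block <- function(Xcol, H, W, Wk, bk, gk, bek, rm, rv, ones) {
    Zraw <- Xcol %*% Wk
    if (s$activation_before_bn) {
      R <- bias_relu(Zraw, bk)
      bn <- bn_forward(R, gk, bek, rm, rv, training)
      pre_pool <- bn$out
    } else {
      bn <- bn_forward(col_affine(Zraw, ones, bk), gk, bek, rm, rv, training)
      R <- bn$out * (bn$out > 0)
      pre_pool <- R
    }
    pl <- maxpool2_hwn(pre_pool, H - kh + 1, W - kw + 1, Nb)
    P <- pl$values
    if (training && s$dropout_rate > 0) {
      keep <- 1 - s$dropout_rate
      mask <- (matrix(runif(length(P)), nrow(P), ncol(P)) < keep) / keep
      Dp <- P * mask
    } else {
      mask <- NULL
      Dp <- P
    }
    list(Xcol = Xcol, R = R, bn = bn, argmax = pl$argmax, mask = mask,
         out = Dp)
  }

  Xcol1 <- im2col_sel(Afull, d$H, d$W, n_all, as.integer(idx), kh, kw)
  b1 <- block(Xcol1, d$H, d$W, params$W1, params$b1, params$g1, params$be1,
              running$m1, running$v1, ones1)
  Xcol2 <- im2col_hwn(b1$out, d$H2, d$W2, Nb, kh, kw)
  b2 <- block(Xcol2, d$H2, d$W2, params$W2, params$b2,
              params$g2, params$be2, running$m2, running$v2, ones2)
  Fm <- b2$out
  dim(Fm) <- c(d$H4 * d$W4, Nb, s$filters2)
  Fm <- aperm(Fm, c(1, 3, 2))
  dim(Fm) <- c(d$H4 * d$W4 * s$filters2, Nb)
  Fm <- t(Fm)
  z <- as.numeric(Fm %*% params$Wd) + params$bd
  p <- 1 / (1 + exp(-z))
  list(p = p, z = z, Fm = Fm, b1 = b1, b2 = b2)
}

# Convenience wrapper for un-laid-out (N x D) inputs.
#' @noRd
cnn_forward <- function(model, X, training = FALSE, params = model$params,
                        running = model$running) {
  Afull <- cnn_layout(X, model$dims)
  cnn_forward_laid(model, Afull, nrow(X), seq_len(nrow(X)), training,
                   params, running)
}

#' @noRd
cnn_backward <- function(model, fw, y, params) {
  s <- model$spec; d <- model$dims
  kh <- s$kernel[1]; kw <- s$kernel[2]
  dz <- (fw$p - y) / length(y)
  gWd <- crossprod(fw$Fm, dz)
  gbd <- sum(dz)
  dF <- matrix(dz, ncol = 1) %*% t(params$Wd)  # N x D_out
  dF <- t(dF)
  dim(dF) <- c(d$H4 * d$W4, s$filters2, length(y))
  dF <- aperm(dF, c(1, 3, 2))
  dim(dF) <- c(d$H4 * d$W4 * length(y), s$filters2)

  block_back <- function(bk, dD, H, W, Wk, gk, want_dx) {
    if (!is.null(bk$mask)) dD <- dD * bk$mask
    dpre <- maxpool2_backward_hwn(dD, bk$argmax, H - kh + 1, W - kw + 1,
                                  length(y))
    if (s$activation_before_bn) {
      bb <- bn_backward(dpre, bk$bn, gk)
      dZ <- bb$dx * (bk$R > 0)
    } else {
      dR <- dpre * (bk$bn$out > 0)
      bb <- bn_backward(dR, bk$bn, gk)
      dZ <- bb$dx
    }
    gW <- crossprod(bk$Xcol, dZ)
    gb <- colSums(dZ)
    dX <- if (want_dx) {
      col2im_hwn(dZ %*% t(Wk), H, W, length(y), kh, kw, nrow(Wk) / (kh * kw))
    } else NULL
    list(gW = gW, gb = gb, gg = bb$dgamma, gbe = bb$dbeta, dX = dX)
  }

  g2 <- block_back(fw$b2, dF, d$H2, d$W2, params$W2, params$g2, want_dx = TRUE)
  g1 <- block_back(fw$b1, g2$dX, d$H, d$W, params$W1, params$g1, want_dx = FALSE)
  list(W1 = g1$gW, b1 = g1$gb, g1 = g1$gg, be1 = g1$gbe,
       W2 = g2$gW, b2 = g2$gb, g2 = g2$gg, be2 = g2$gbe,
       Wd = gWd, bd = gbd)
}

#' @noRd
bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' @noRd
flatten_features <- function(x) {
  if (is.matrix(x)) return(x)
  dm <- dim(x)
  if (length(dm) != 4) stopf("expected an (epochs, freq, time, channel) array")
  matrix(x, dm[1], prod(dm[-1]))
}

#' Fit the epoch-level CNN
#'
#' Minimizes binary cross-entropy with Adam. Training is reproducible from
#' `spec$seed` (initialization, shuffling and dropout all derive from it).
#' With `early_stop = "internal_val"` a validation set (either `val_x` —
#' typically epochs of held-aside training subjects — or a random
#' `val_frac` split) is monitored with patience, and the best weights are
#' restored.
#'
#' @param model an `eeg_cnn` from [build_cnn()].
#' @param x training tensors: `(epochs, freqs, times, channels)` array or an
#'   already-flattened `(epochs, features)` matrix (standardized upstream).
#' @param y binary labels (0/1), both classes present.
#' @param val_x,val_y optional monitoring set (same format).
#' @return The fitted model; `model$history` holds per-pass train/validation
#'   loss.
#' @export
fit_epoch_classifier <- function(model, x, y, val_x = NULL, val_y = NULL) {
  stopifnot(inherits(model, "eeg_cnn"))
  X <- flatten_features(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stopf("training labels contain a single class")
  if (ncol(X) != prod(model$input_dim)) {
    stopf("feature dimension %d does not match input_dim (%s)",
          ncol(X), paste(model$input_dim, collapse = " x "))
  }
  s <- model$spec
  monitor <- s$early_stop != "none"
  with_seed(s$seed, {
    if (monitor && is.null(val_x) && s$early_stop == "internal_val") {
      n_val <- max(2L, round(s$val_frac * nrow(X)))
      vi <- sample.int(nrow(X), n_val)
      val_x <- X[vi, , drop = FALSE]; val_y <- y[vi]
      X <- X[-vi, , drop = FALSE]; y <- y[-vi]
    }
    if (monitor && is.null(val_x)) {
      stopf("early_stop = '%s' requires a monitoring set", s$early_stop)
    }
    Xv <- if (monitor) flatten_features(val_x) else NULL
    Afull <- cnn_layout(X, model$dims)
    Av <- if (monitor) cnn_layout(Xv, model$dims) else NULL
    params <- cnn_init_params(model)
    running <- cnn_init_running(s)
    adam_m <- lapply(params, function(p) p * 0)
    adam_v <- lapply(params, function(p) p * 0)
    step <- 0L
    lr <- s$learning_rate
    best <- list(loss = Inf, params = params, running = running, pass = 0L)
    wait <- 0L
    hist <- NULL
    for (pass in seq_len(s$max_train_epochs)) {
      ord <- sample.int(nrow(X))
      batches <- split(ord, ceiling(seq_along(ord) / s$batch_size))
      tot_loss <- 0; tot_n <- 0
      for (bi in batches) {
        if (length(bi) < 2) next
        fw <- cnn_forward_laid(model, Afull, nrow(X), bi, training = TRUE,
                               params = params, running = running)
        loss <- bce_loss(fw$p, y[bi])
        if (!is.finite(loss)) stopf("non-finite training loss at pass %d", pass)
        tot_loss <- tot_loss + loss * length(bi); tot_n <- tot_n + length(bi)
        for (blk in c("1", "2")) {
          bn <- fw[[paste0("b", blk)]]$bn
          running[[paste0("m", blk)]] <-
            BN_MOMENTUM * running[[paste0("m", blk)]] + (1 - BN_MOMENTUM) * bn$mu
          running[[paste0("v", blk)]] <-
            BN_MOMENTUM * running[[paste0("v", blk)]] + (1 - BN_MOMENTUM) * bn$v
        }
        gr <- cnn_backward(model, fw, y[bi], params)
        step <- step + 1L
        for (nm in names(params)) {
          adam_m[[nm]] <- 0.9 * adam_m[[nm]] + 0.1 * gr[[nm]]
          adam_v[[nm]] <- 0.999 * adam_v[[nm]] + 0.001 * gr[[nm]]^2
          mh <- adam_m[[nm]] / (1 - 0.9^step)
          vh <- adam_v[[nm]] / (1 - 0.999^step)
          params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + 1e-8)
        }
      }
      train_loss <- tot_loss / tot_n
      val_loss <- NA_real_
      if (monitor) {
        pv <- cnn_forward_laid(model, Av, nrow(Xv), seq_len(nrow(Xv)),
                               training = FALSE, params = params,
                               running = running)$p
        val_loss <- bce_loss(pv, as.numeric(val_y))
        if (val_loss < best$loss - 1e-6) {
          best <- list(loss = val_loss, params = params, running = running,
                       pass = pass)
          wait <- 0L
        } else {
          wait <- wait + 1L
        }
      }
      hist <- rbind(hist, data.frame(pass = pass, train_loss = train_loss,
                                     val_loss = val_loss))
      if (monitor && pass >= s$min_train_epochs && wait >= s$patience) break
    }
    if (monitor && is.finite(best$loss)) {
      params <- best$params
      running <- best$running
    }
    model$params <- params
    model$running <- running
    model$history <- hist
    model$trained <- TRUE
    model
  })
}

#' Predict epoch-level class-1 probabilities
#'
#' Deterministic inference: dropout inactive, batch normalization uses the
#' running statistics. Each output is the sigmoid head's probability that
#' the epoch belongs to class 1.
#'
#' @param model a built (and normally fitted) `eeg_cnn`.
#' @param x tensors or flattened feature matrix (standardized with the
#'   training scaler).
#' @return Numeric vector of probabilities in `[0, 1]`, one per epoch.
#' @export
predict_epoch_probabilities <- function(model, x) {
  stopifnot(inherits(model, "eeg_cnn"))
  X <- flatten_features(x)
  if (ncol(X) != prod(model$input_dim)) {
    stopf("feature dimension %d does not match input_dim (%s)",
          ncol(X), paste(model$input_dim, collapse = " x "))
  }
  # chunked inference keeps the im2col expansion bounded
  chunks <- split(seq_len(nrow(X)), ceiling(seq_len(nrow(X)) / 256))
  unlist(lapply(chunks, function(ix) {
    cnn_forward(model, X[ix, , drop = FALSE], training = FALSE)$p
  }), use.names = FALSE)
}

#' @export
print.eeg_cnn <- function(x, ...) {
  cat(sprintf("<eeg_cnn> input %s, %s\n",
              paste(x$input_dim, collapse = " x "),
              if (x$trained) sprintf("trained (%d passes)", max(x$history$pass))
              else "untrained"))
  invisible(x)
}
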