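# Gated recurrent unit decoder, hand-rolled: batched forward pass, full
# backpropagation through time, Adam with L2 weight decay and global-norm
# gradient clipping, and analytic input gradients for sensitivity maps.
#
# Gate equations (elementwise, sigma = logistic):
#   r(t) = sigma(W_ir x(t) + b_ir + W_hr h(t-1) + b_hr)
#   z(t) = sigma(W_iz x(t) + b_iz + W_hz h(t-1) + b_hz)
#   n(t) = tanh (W_in x(t) + b_in + r(t) * (W_hn h(t-1) + b_hn))
#   h(t) = (1 - z(t)) * n(t) + z(t) * h(t-1),  h(0) = 0
#   y(t) = w_out . h(t)
# Loss per trial: 1 - Pearson r(y_pred, y_true); batch loss is the mean.

#' GRU training configuration
#'
#' Defaults are the published winning hyperparameters: one layer, hidden size
#' 300, learning rate 0.0023, L2 weight decay 0.0052, gradient clipping at
#' global norm 1, no dropout, batch size 12, 7 training epochs.
#' @param hidden_size,learning_rate,l2,clip,batch_size,epochs,dropout scalars.
#' @export
gru_config <- function(hidden_size = 300, learning_rate = 0.0023, l2 = 0.0052,
                       clip = 1, batch_size = 12, epochs = 7, dropout = 0) {
  stopifnot(hidden_size >= 1, learning_rate > 0, l2 >= 0, clip > 0,
            batch_size >= 1, epochs >= 1, dropout == 0)
  list(hidden_size = as.integer(hidden_size), learning_rate = learning_rate,
       l2 = l2, clip = clip, batch_size = as.integer(batch_size),
       epochs = as.integer(epochs), dropout = dropout)
}

#' @keywords internal
#' @noRd
gru_init <- function(n_input, hidden, seed) {
  # PyTorch-style uniform(-1/sqrt(H), 1/sqrt(H)) initialization
  bnd <- 1 / sqrt(hidden)
  with_seed(seed, {
    u <- function(nr, nc) matrix(stats::runif(nr * nc, -bnd, bnd), nr, nc)
    list(
      Wir = u(hidden, n_input), Wiz = u(hidden, n_input), Win = u(hidden, n_input),
      Whr = u(hidden, hidden), Whz = u(hidden, hidden), Whn = u(hidden, hidden),
      bir = stats::runif(hidden, -bnd, bnd), bhr = stats::runif(hidden, -bnd, bnd),
      biz = stats::runif(hidden, -bnd, bnd), bhz = stats::runif(hidden, -bnd, bnd),
      bin = stats::runif(hidden, -bnd, bnd), bhn = stats::runif(hidden, -bnd, bnd),
      w_out = stats::runif(hidden, -bnd, bnd)
    )
  })
}

#' @keywords internal
#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass over a batch. X: list over time of (B x K) matrices (or a
# T x B x K array). Returns predictions (T x B) and, if keep_states, the gate
# activations needed for BPTT.
#' @keywords internal
#' @noRd
gru_forward <- function(par, X, keep_states = FALSE) {
  T_ <- length(X)
  B <- nrow(X[[1]])
  H <- length(par$w_out)
  h <- matrix(0, B, H)
  Y <- matrix(0, T_, B)
  st <- if (keep_states) vector("list", T_) else NULL
  tWir <- t(par$Wir); tWiz <- t(par$Wiz); tWin <- t(par$Win)
  tWhr <- t(par$Whr); tWhz <- t(par$Whz); tWhn <- t(par$Whn)
  for (t in seq_len(T_)) {
    x <- X[[t]]
    r <- sigmoid(x %*% tWir + h %*% tWhr +
                   rep(par$bir + par$bhr, each = B))
    z <- sigmoid(x %*% tWiz + h %*% tWhz +
                   rep(par$biz + par$bhz, each = B))
    hn <- h %*% tWhn + rep(par$bhn, each = B)
    n <- tanh(x %*% tWin + rep(par$bin, each = B) + r * hn)
    h_new <- (1 - z) * n + z * h
    Y[t, ] <- h_new %*% par$w_out
    if (keep_states) st[[t]] <- list(r = r, z = z, n = n, hn = hn, h_prev = h)
    h <- h_new
  }
  list(Y = Y, states = st, h_last = h)
}

# BPTT given dY (T x B, gradient of the loss w.r.t. predictions).
# Returns weight gradients (same shapes as par) and dX (list over time, B x K).
#' @keywords internal
#' @noRd
gru_backward <- function(par, X, fw, dY, want_dx = FALSE) {
  T_ <- length(X)
  B <- nrow(X[[1]])
  H <- length(par$w_out)
  g <- lapply(par, function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p)))
  dX <- if (want_dx) vector("list", T_) else NULL
  dh_next <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    s <- fw$states[[t]]
    h_new_grad_from_y <- outer(dY[t, ], par$w_out) # B x H
    h_t <- (1 - s$z) * s$n + s$z * s$h_prev
    g$w_out <- g$w_out + as.numeric(t(h_t) %*% dY[t, ])
    dh <- h_new_grad_from_y + dh_next
    dn <- dh * (1 - s$z)
    dz <- dh * (s$h_prev - s$n)
    dh_prev <- dh * s$z
    dn_pre <- dn * (1 - s$n^2)
    dr <- dn_pre * s$hn
    dhn <- dn_pre * s$r
    dz_pre <- dz * s$z * (1 - s$z)
    dr_pre <- dr * s$r * (1 - s$r)
    x <- X[[t]]
    g$Wir <- g$Wir + t(dr_pre) %*% x
    g$Wiz <- g$Wiz + t(dz_pre) %*% x
    g$Win <- g$Win + t(dn_pre) %*% x
    g$Whr <- g$Whr + t(dr_pre) %*% s$h_prev
    g$Whz <- g$Whz + t(dz_pre) %*% s$h_prev
    g$Whn <- g$Whn + t(dhn) %*% s$h_prev
    g$bir <- g$bir + colSums(dr_pre); g$bhr <- g$bhr + colSums(dr_pre)
    g$biz <- g$biz + colSums(dz_pre); g$bhz <- g$bhz + colSums(dz_pre)
    g$bin <- g$bin + colSums(dn_pre); g$bhn <- g$bhn + colSums(dhn)
    if (want_dx) {
      dX[[t]] <- dr_pre %*% par$Wir + dz_pre %*% par$Wiz + dn_pre %*% par$Win
    }
    dh_next <- dh_prev + dr_pre %*% par$Whr + dz_pre %*% par$Whz +
      dhn %*% par$Whn
  }
  list(grads = g, dX = dX)
}

# Correlation loss 1 - r and its gradient w.r.t. predictions, per column of
# (T x B) matrices; eps guards the variance denominator.
#' @keywords internal
#' @noRd
corr_loss <- function(Y, Ytrue, eps = 1e-8) {
  T_ <- nrow(Y)
  B <- ncol(Y)
  loss <- numeric(B)
  dY <- matrix(0, T_, B)
  for (b in seq_len(B)) {
    yp <- Y[, b]; yt <- Ytrue[, b]
    ypc <- yp - mean(yp); ytc <- yt - mean(yt)
    sp <- sqrt(sum(ypc^2) + eps)
    st_ <- sqrt(sum(ytc^2) + eps)
    cov <- sum(ypc * ytc)
    r <- cov / (sp * st_)
    loss[b] <- 1 - r
    # d(1-r)/dyp = -(ytc / (sp*st) - cov * ypc / (sp^3 * st))
    dY[, b] <- -(ytc / (sp * st_) - cov * ypc / (sp^3 * st_))
  }
  list(loss = mean(loss), dY = dY / B)
}

#' Fit a GRU pupil decoder
#'
#' Trains the gated recurrent unit on (component series, pupil trace) pairs
#' with the correlation loss (1 - Pearson r per trial, averaged per batch),
#' Adam updates with L2 weight decay, and gradient clipping by global norm.
#' The hidden state starts at zero for every trial. Fixed seed gives
#' reproducible weights on the same platform.
#'
#' @param series list of `ComponentSeries` (or `n_components x T` matrices),
#'   one per training trial; all trials must share T.
#' @param pupil list of length-`T` numeric traces (variance-normalized).
#' @param config a [gru_config()].
#' @param seed integer seed (initialization and batch shuffling).
#' @return object of class `GRUDecoder`: parameter list `par`, `config`,
#'   `n_input`, `loss_history`.
#' @export
fit_gru <- function(series, pupil, config = gru_config(), seed = 1) {
  stopifnot(length(series) == length(pupil), length(series) >= 1)
  mats <- lapply(series, function(s) if (inherits(s, "ComponentSeries")) s$scores else as.matrix(s))
  K <- nrow(mats[[1]])
  T_ <- ncol(mats[[1]])
  for (m in mats) stopifnot(nrow(m) == K, ncol(m) == T_)
  n_trials <- length(mats)
  par <- gru_init(K, config$hidden_size, substream_seed(seed, 1L))
  adam <- list(m = lapply(par, function(p) p * 0),
               v = lapply(par, function(p) p * 0), t = 0)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  loss_hist <- numeric(0)
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(substream_seed(seed, 100L + epoch), sample.int(n_trials))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bt in batches) {
      B <- length(bt)
      X <- lapply(seq_len(T_), function(t) {
        do.call(rbind, lapply(bt, function(i) mats[[i]][, t]))
      })
      Ytrue <- do.call(cbind, lapply(bt, function(i) pupil[[i]]))
      fw <- gru_forward(par, X, keep_states = TRUE)
      cl <- corr_loss(fw$Y, Ytrue)
      if (!is.finite(cl$loss)) {
        stop("non-finite GRU loss at epoch ", epoch,
             " (batch of ", B, "); inspect inputs/learning rate")
      }
      loss_hist <- c(loss_hist, cl$loss)
      bw <- gru_backward(par, X, fw, cl$dY)
      g <- bw$grads
      # clip raw gradients by global norm, then apply L2 weight decay inside
      # the update (the order the reference training loop uses)
      gn <- sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
      if (is.finite(gn) && gn > config$clip) {
        g <- lapply(g, function(x) x * (config$clip / gn))
      }
      if (config$l2 > 0) {
        g <- mapply(function(gi, pi) gi + config$l2 * pi, g, par,
                    SIMPLIFY = FALSE)
      }
      adam$t <- adam$t + 1
      for (nm in names(par)) {
        adam$m[[nm]] <- beta1 * adam$m[[nm]] + (1 - beta1) * g[[nm]]
        adam$v[[nm]] <- beta2 * adam$v[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- adam$m[[nm]] / (1 - beta1^adam$t)
        vhat <- adam$v[[nm]] / (1 - beta2^adam$t)
        par[[nm]] <- par[[nm]] - config$learning_rate * mhat /
          (sqrt(vhat) + adam_eps)
      }
    }
  }
  structure(list(par = par, config = config, n_input = K,
                 loss_history = loss_hist),
            class = "GRUDecoder")
}

#' @rdname predict.LinearDecoder
#' @export
predict.GRUDecoder <- function(object, X, ...) {
  S <- if (inherits(X, "ComponentSeries")) X$scores else as.matrix(X)
  if (nrow(S) != object$n_input) {
    stop("component count mismatch: decoder has ", object$n_input,
         ", input has ", nrow(S))
  }
  Xl <- lapply(seq_len(ncol(S)), function(t) matrix(S[, t], 1))
  as.numeric(gru_forward(object$par, Xl)$Y)
}

#' Mean input sensitivities of a GRU decoder
#'
#' Per trial, the gradient of the summed prediction `sum_t y(t)` with respect
#' to the input sequence (a `T x K` matrix) is computed by backpropagation
#' through time, averaged over the input time axis, and then averaged over
#' trials. For a GRU that implements a static linear map `y = w . x(t)` this
#' returns exactly `w`, so the sensitivities play the role of linear decoder
#' weights in map integration.
#'
#' @param decoder a [fit_gru()] object.
#' @param series list of `ComponentSeries` or matrices.
#' @return numeric length-`n_input` vector.
#' @export
gru_input_sensitivities <- function(decoder, series) {
  stopifnot(inherits(decoder, "GRUDecoder"))
  mats <- lapply(series, function(s) if (inherits(s, "ComponentSeries")) s$scores else as.matrix(s))
  acc <- numeric(decoder$n_input)
  for (m in mats) {
    T_ <- ncol(m)
    Xl <- lapply(seq_len(T_), function(t) matrix(m[, t], 1))
    fw <- gru_forward(decoder$par, Xl, keep_states = TRUE)
    dY <- matrix(1, T_, 1)
    bw <- gru_backward(decoder$par, Xl, fw, dY, want_dx = TRUE)
    G <- do.call(rbind, bw$dX) # T x K
    if (any(!is.finite(G))) stop("non-finite GRU input gradients")
    acc <- acc + colMeans(G)
  }
  acc / length(mats)
}
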