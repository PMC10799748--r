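## Minimal neural-network core: a dense feed-forward classifier
## (batch-normalized ReLU stack with dropout and a 2-unit softmax head) and a
## single-layer LSTM over embedded residue sequences with a sigmoid head.
## Both are trained with Adam on mini-batches.  Written as plain matrix code;
## gradients are verified against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- Adam ----------------------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (k in names(params)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * grads[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- st$m[[k]] / (1 - beta1^st$t)
    vhat <- st$v[[k]] / (1 - beta2^st$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

## ---- dense network -------------------------------------------------------

mlp_init <- function(input_dim, units, n_classes = 2L) {
  dims <- c(input_dim, units)
  params <- list()
  for (l in seq_along(units)) {
    sd <- sqrt(2 / dims[l])  # He initialization for ReLU
    params[[paste0("W", l)]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                                    sd = sd),
                                       dims[l], dims[l + 1L])
    params[[paste0("b", l)]] <- numeric(dims[l + 1L])
    params[[paste0("gamma", l)]] <- rep(1, dims[l + 1L])
    params[[paste0("beta", l)]] <- numeric(dims[l + 1L])
  }
  sd <- sqrt(2 / dims[length(dims)])
  params$Wo <- matrix(stats::rnorm(units[length(units)] * n_classes, sd = sd),
                      units[length(units)], n_classes)
  params$bo <- numeric(n_classes)
  params
}

bn_eps <- 1e-5

mlp_forward <- function(params, X, units, dropout, training = FALSE,
                        running = NULL) {
  cache <- list()
  H <- X
  for (l in seq_along(units)) {
    Z <- sweep(H %*% params[[paste0("W", l)]], 2,
               params[[paste0("b", l)]], `+`)
    if (training) {
      mu <- colMeans(Z)
      va <- colMeans(sweep(Z, 2, mu)^2)
    } else {
      mu <- running$mean[[l]]; va <- running$var[[l]]
    }
    Zc <- sweep(Z, 2, mu)
    inv_sd <- 1 / sqrt(va + bn_eps)
    Zhat <- sweep(Zc, 2, inv_sd, `*`)
    A <- sweep(sweep(Zhat, 2, params[[paste0("gamma", l)]], `*`), 2,
               params[[paste0("beta", l)]], `+`)
    R <- pmax(A, 0)
    mask <- NULL
    p_drop <- dropout[l]
    if (training && !is.na(p_drop) && p_drop > 0) {
      mask <- matrix(stats::rbinom(length(R), 1L, 1 - p_drop),
                     nrow(R)) / (1 - p_drop)
      R <- R * mask
    }
    cache[[l]] <- list(H_in = H, Z = Z, mu = mu, va = va, Zhat = Zhat,
                       A = A, mask = mask, inv_sd = inv_sd)
    H <- R
  }
  logits <- sweep(H %*% params$Wo, 2, params$bo, `+`)
  logits <- logits - apply(logits, 1, max)
  expz <- exp(logits)
  probs <- expz / rowSums(expz)
  list(probs = probs, H_last = H, cache = cache)
}

mlp_backward <- function(params, fwd, Y, units, dropout) {
  m <- nrow(Y)
  grads <- list()
  dlogits <- (fwd$probs - Y) / m
  grads$Wo <- t(fwd$H_last) %*% dlogits
  grads$bo <- colSums(dlogits)
  dH <- dlogits %*% t(params$Wo)
  for (l in rev(seq_along(units))) {
    cc <- fwd$cache[[l]]
    if (!is.null(cc$mask)) dH <- dH * cc$mask
    dA <- dH * (cc$A > 0)
    g <- params[[paste0("gamma", l)]]
    grads[[paste0("gamma", l)]] <- colSums(dA * cc$Zhat)
    grads[[paste0("beta", l)]] <- colSums(dA)
    dZhat <- sweep(dA, 2, g, `*`)
    # batch-norm backward
    mb <- nrow(dZhat)
    Zc <- sweep(cc$Z, 2, cc$mu)
    dvar <- colSums(dZhat * Zc) * (-0.5) * cc$inv_sd^3
    dmu <- colSums(sweep(dZhat, 2, -cc$inv_sd, `*`)) +
      dvar * colMeans(-2 * Zc)
    dZ <- sweep(dZhat, 2, cc$inv_sd, `*`) +
      sweep(2 * Zc / mb, 2, dvar, `*`) +
      matrix(dmu / mb, mb, length(dmu), byrow = TRUE)
    grads[[paste0("W", l)]] <- t(cc$H_in) %*% dZ
    grads[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1L) dH <- dZ %*% t(params[[paste0("W", l)]])
  }
  grads[names(params)]
}

#' Train the dense-network classifier
#'
#' Seven batch-normalized ReLU dense layers (512, 256, 128, 128, 64, 128,
#' 256 units) with dropout (0.5, 0.4, 0.4, 0.4, 0.4 after layers 1-5 and 0.5
#' after layer 7) and a 2-unit softmax head, trained with Adam (learning rate
#' 0.001) on categorical cross-entropy; the positive-class probability is the
#' second softmax component.
#'
#' @param X Numeric feature matrix (already scaled).
#' @param y Integer 0/1 labels (1 = positive).
#' @param units,dropout Layer widths and dropout rates.
#' @param lr Learning rate.
#' @param epochs,batch_size Training schedule.
#' @param seed Integer seed (initialization, shuffling, dropout).
#' @return An object of class `dense_net`.
#' @export
train_dense_net <- function(X, y, units = c(512L, 256L, 128L, 128L, 64L,
                                            128L, 256L),
                            dropout = c(0.5, 0.4, 0.4, 0.4, 0.4, NA, 0.5),
                            lr = 0.001, epochs = 50L, batch_size = 32L,
                            seed = 1L) {
  stopifnot(length(dropout) == length(units))
  n <- nrow(X)
  Y <- cbind(1 - y, y)
  with_seed(seed, {
    params <- mlp_init(ncol(X), units)
    opt <- adam_new(params)
    run_mean <- lapply(units, function(u) numeric(u))
    run_var <- lapply(units, function(u) rep(1, u))
    momentum <- 0.9
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        if (length(idx) < 2L) next  # batch norm needs >= 2 rows
        fwd <- mlp_forward(params, X[idx, , drop = FALSE], units, dropout,
                           training = TRUE)
        for (l in seq_along(units)) {
          run_mean[[l]] <- momentum * run_mean[[l]] +
            (1 - momentum) * fwd$cache[[l]]$mu
          run_var[[l]] <- momentum * run_var[[l]] +
            (1 - momentum) * fwd$cache[[l]]$va
        }
        grads <- mlp_backward(params, fwd, Y[idx, , drop = FALSE], units,
                              dropout)
        upd <- adam_step(params, grads, opt, lr)
        params <- upd$params; opt <- upd$state
      }
    }
    structure(list(params = params, units = units, dropout = dropout,
                   running = list(mean = run_mean, var = run_var)),
              class = "dense_net")
  })
}

#' @rdname train_dense_net
#' @param object A `dense_net`.
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict_dense_net <- function(object, X, ...) {
  fwd <- mlp_forward(object$params, X, object$units, object$dropout,
                     training = FALSE, running = object$running)
  fwd$probs[, 2L]
}

## ---- LSTM ----------------------------------------------------------------

lstm_init <- function(vocab = 21L, emb_dim = 64L, hidden = 64L) {
  g4 <- 4L * hidden
  list(E = matrix(stats::rnorm(vocab * emb_dim, sd = 0.1), vocab, emb_dim),
       W = matrix(stats::rnorm(emb_dim * g4, sd = 1 / sqrt(emb_dim)),
                  emb_dim, g4),
       U = matrix(stats::rnorm(hidden * g4, sd = 1 / sqrt(hidden)),
                  hidden, g4),
       b = c(rep(0, hidden), rep(1, hidden), rep(0, 2L * hidden)),  # forget bias 1
       wo = matrix(stats::rnorm(hidden, sd = 1 / sqrt(hidden)), hidden, 1L),
       bo = 0)
}

# forward over a batch of integer sequences (B x T), returning caches for BPTT
lstm_forward <- function(params, seqs) {
  B <- nrow(seqs); Tn <- ncol(seqs)
  H <- nrow(params$wo)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- params$E[seqs[, t], , drop = FALSE]
    z <- x %*% params$W + h %*% params$U +
      matrix(params$b, B, 4L * H, byrow = TRUE)
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    o <- sigmoid(z[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_new <- o * tc
    steps[[t]] <- list(x = x, h_prev = h, c_prev = c_prev, i = i, f = f,
                       o = o, g = g, c = cc, tc = tc)
    h <- h_new
  }
  p <- sigmoid(drop(h %*% params$wo) + params$bo)
  list(p = p, h_last = h, steps = steps)
}

lstm_backward <- function(params, fwd, seqs, y) {
  B <- nrow(seqs); Tn <- ncol(seqs); H <- nrow(params$wo)
  grads <- lapply(params, function(p) p * 0)
  dlogit <- matrix((fwd$p - y) / B, B, 1L)           # BCE through sigmoid
  grads$wo <- t(fwd$h_last) %*% dlogit
  grads$bo <- sum(dlogit)
  dh <- dlogit %*% t(params$wo)
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    st <- fwd$steps[[t]]
    do <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                do * st$o * (1 - st$o),
                dg * (1 - st$g^2))
    grads$W <- grads$W + t(st$x) %*% dz
    grads$U <- grads$U + t(st$h_prev) %*% dz
    grads$b <- grads$b + colSums(dz)
    dx <- dz %*% t(params$W)
    ids <- seqs[, t]
    for (u in unique(ids)) {
      rows <- which(ids == u)
      grads$E[u, ] <- grads$E[u, ] + colSums(dx[rows, , drop = FALSE])
    }
    dh <- dz %*% t(params$U)
    dc <- dc * st$f
  }
  grads
}

#' Train the LSTM sequence classifier
#'
#' Residues are integer-mapped (canonical alphabetical rank, dummy = 21),
#' embedded (dimension 64), passed through a single 64-unit LSTM layer, and
#' the final hidden state feeds a sigmoid output unit; trained with Adam on
#' binary cross-entropy.
#'
#' @param seqs Integer matrix (fragments x positions), values in 1..21.
#' @param y Integer 0/1 labels.
#' @param emb_dim,hidden Embedding and hidden dimensions.
#' @param lr,epochs,batch_size Training schedule.
#' @param seed Integer seed.
#' @return An object of class `lstm_net`.
#' @export
train_lstm <- function(seqs, y, emb_dim = 64L, hidden = 64L, lr = 0.001,
                       epochs = 10L, batch_size = 32L, seed = 1L) {
  n <- nrow(seqs)
  with_seed(seed, {
    params <- lstm_init(21L, emb_dim, hidden)
    opt <- adam_new(params)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        fwd <- lstm_forward(params, seqs[idx, , drop = FALSE])
        grads <- lstm_backward(params, fwd, seqs[idx, , drop = FALSE], y[idx])
        upd <- adam_step(params, grads, opt, lr)
        params <- upd$params; opt <- upd$state
      }
    }
    structure(list(params = params), class = "lstm_net")
  })
}

#' @rdname train_lstm
#' @param object An `lstm_net`.
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict_lstm <- function(object, seqs, ...) {
  lstm_forward(object$params, seqs)$p
}

#' Integer-map fragment residue strings for the LSTM
#'
#' @param fragments Character vector of residue strings (equal length).
#' @return Integer matrix (fragments x positions), values in 1..21.
#' @export
fragments_to_int <- function(fragments) {
  L <- nchar(fragments[1])
  t(vapply(fragments, function(f) residue_index(split_residues(f)),
           integer(L)))
}
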