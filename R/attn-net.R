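# Internal numerical core of the attention recurrent classifier.
#
# Shapes: B samples per batch, T timesteps, F features, H hidden units.
# Gate order in the LSTM weight matrices is (input, forget, output, cell).
# Masking contract: inputs at padded steps are zeroed before the attention
# layer and the recurrent state carries through unchanged, so padded values
# can never reach the prediction.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

trainable <- c("Wa", "Wx", "Wh", "b", "wo", "bo")

# feature-wise standardization fitted on unmasked days of the training split
fit_scaler <- function(tensor) {
  Fn <- tensor$F
  mu <- numeric(Fn); sd_ <- numeric(Fn)
  obs <- tensor$mask == 1
  for (f in seq_len(Fn)) {
    v <- tensor$values[, , f][obs]
    mu[f] <- mean(v)
    sd_[f] <- stats::sd(v)
  }
  sd_[!is.finite(sd_) | sd_ < 1e-8] <- 1
  list(mean = mu, sd = sd_)
}

# standardize (optionally) and re-zero padded steps
apply_scaler <- function(tensor, scaler) {
  V <- tensor$values
  M <- tensor$mask
  Fn <- tensor$F
  for (f in seq_len(Fn)) {
    x <- matrix(V[, , f], nrow = dim(V)[1])
    if (!is.null(scaler)) x <- (x - scaler$mean[f]) / scaler$sd[f]
    V[, , f] <- x * M
  }
  list(values = V, mask = M)
}

init_params <- function(T_, F_, H, config) {
  glorot <- function(nr, nc)
    matrix(runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
  gate_mult <- if (config$cell == "lstm") 4L else 1L
  Wa <- if (config$attention_weight_sharing == "per-timestep") {
    lapply(seq_len(T_), function(t) matrix(rnorm(F_ * F_, sd = 0.01), F_, F_))
  } else matrix(rnorm(F_ * F_, sd = 0.01), F_, F_)
  b <- numeric(gate_mult * H)
  if (config$cell == "lstm") b[H + seq_len(H)] <- 1  # forget-gate bias
  list(Wa = Wa,
       Wx = glorot(F_, gate_mult * H),
       Wh = glorot(H, gate_mult * H),
       b = b,
       wo = glorot(H, 1L),
       bo = 0,
       T = T_)
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like)
  else if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
  else numeric(length(p))
}

net_forward <- function(X, M, params, config, cache = FALSE) {
  dims <- dim(X)
  B <- dims[1]; T_ <- dims[2]; F_ <- dims[3]
  H <- if (config$cell == "lstm") length(params$b) %/% 4L
       else length(params$b)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  caches <- if (cache) vector("list", T_)
  attention <- if (cache) array(0, dim = dims)
  bmat <- matrix(params$b, B, length(params$b), byrow = TRUE)
  for (t in seq_len(T_)) {
    Xt <- matrix(X[, t, ], B, F_)
    Wt <- if (is.list(params$Wa)) params$Wa[[t]] else params$Wa
    Z <- Xt %*% t(Wt)
    A <- softmax_rows(Z)
    Xa <- Xt * A
    m <- M[, t]
    if (config$cell == "lstm") {
      G <- Xa %*% params$Wx + h %*% params$Wh + bmat
      i_ <- sigmoid(G[, seq_len(H), drop = FALSE])
      f_ <- sigmoid(G[, H + seq_len(H), drop = FALSE])
      o_ <- sigmoid(G[, 2L * H + seq_len(H), drop = FALSE])
      g_ <- tanh(G[, 3L * H + seq_len(H), drop = FALSE])
      c_new <- f_ * cc + i_ * g_
      tc <- tanh(c_new)
      h_new <- o_ * tc
      if (cache)
        caches[[t]] <- list(Xt = Xt, A = A, Xa = Xa, i = i_, f = f_, o = o_,
                            g = g_, c_prev = cc, c_new = c_new, tc = tc,
                            h_prev = h, m = m)
      h <- m * h_new + (1 - m) * h
      cc <- m * c_new + (1 - m) * cc
    } else {
      G <- Xa %*% params$Wx + h %*% params$Wh + bmat
      h_new <- tanh(G)
      if (cache)
        caches[[t]] <- list(Xt = Xt, A = A, Xa = Xa, h_new = h_new,
                            h_prev = h, m = m)
      h <- m * h_new + (1 - m) * h
    }
    if (cache) attention[, t, ] <- A
  }
  logit <- h %*% params$wo + params$bo
  out <- list(p = as.numeric(sigmoid(logit)), h = h)
  if (cache) {
    out$caches <- caches
    out$attention <- attention
    out$B <- B; out$T <- T_; out$F <- F_; out$H <- H
  }
  out
}

net_backward <- function(fw, y, params, config) {
  B <- fw$B; T_ <- fw$T; H <- fw$H
  grads <- list(Wa = zero_like(params$Wa), Wx = zero_like(params$Wx),
                Wh = zero_like(params$Wh), b = zero_like(params$b),
                wo = zero_like(params$wo), bo = 0)
  dlogit <- matrix((fw$p - y) / B, ncol = 1)
  grads$wo <- t(fw$h) %*% dlogit
  grads$bo <- sum(dlogit)
  dh <- dlogit %*% t(params$wo)
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    cachet <- fw$caches[[t]]
    m <- cachet$m
    dh_new <- dh * m
    dh_carry <- dh * (1 - m)
    if (config$cell == "lstm") {
      dc_new <- dc * m
      dc_carry <- dc * (1 - m)
      do_ <- dh_new * cachet$tc
      dtc <- dh_new * cachet$o
      dct <- dc_new + dtc * (1 - cachet$tc^2)
      df <- dct * cachet$c_prev
      di <- dct * cachet$g
      dg <- dct * cachet$i
      dc_prev <- dct * cachet$f
      dG <- cbind(di * cachet$i * (1 - cachet$i),
                  df * cachet$f * (1 - cachet$f),
                  do_ * cachet$o * (1 - cachet$o),
                  dg * (1 - cachet$g^2))
      grads$Wx <- grads$Wx + t(cachet$Xa) %*% dG
      grads$Wh <- grads$Wh + t(cachet$h_prev) %*% dG
      grads$b <- grads$b + colSums(dG)
      dXa <- dG %*% t(params$Wx)
      dh <- dh_carry + dG %*% t(params$Wh)
      dc <- dc_carry + dc_prev
    } else {
      dG <- dh_new * (1 - cachet$h_new^2)
      grads$Wx <- grads$Wx + t(cachet$Xa) %*% dG
      grads$Wh <- grads$Wh + t(cachet$h_prev) %*% dG
      grads$b <- grads$b + colSums(dG)
      dXa <- dG %*% t(params$Wx)
      dh <- dh_carry + dG %*% t(params$Wh)
    }
    # attention backward: a = softmax(z), y = x * a, z = x Wa^T
    dA <- dXa * cachet$Xt
    dZ <- cachet$A * (dA - rowSums(dA * cachet$A))
    dWt <- t(dZ) %*% cachet$Xt
    if (is.list(grads$Wa)) grads$Wa[[t]] <- grads$Wa[[t]] + dWt
    else grads$Wa <- grads$Wa + dWt
  }
  grads
}

adam_init <- function(params) {
  list(params = params,
       m = lapply(params[trainable], zero_like),
       v = lapply(params[trainable], zero_like),
       step = 0L)
}

adam_step <- function(params, grads, opt, config) {
  opt$step <- opt$step + 1L
  lr <- config$learning_rate
  b1 <- config$beta1; b2 <- config$beta2; eps <- config$epsilon
  corr1 <- 1 - b1^opt$step
  corr2 <- 1 - b2^opt$step
  upd <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  for (nm in trainable) {
    if (is.list(params[[nm]])) {
      for (k in seq_along(params[[nm]])) {
        r <- upd(params[[nm]][[k]], grads[[nm]][[k]],
                 opt$m[[nm]][[k]], opt$v[[nm]][[k]])
        params[[nm]][[k]] <- r$p
        opt$m[[nm]][[k]] <- r$m
        opt$v[[nm]][[k]] <- r$v
      }
    } else {
      r <- upd(params[[nm]], grads[[nm]], opt$m[[nm]], opt$v[[nm]])
      params[[nm]] <- r$p
      opt$m[[nm]] <- r$m
      opt$v[[nm]] <- r$v
    }
  }
  opt$params <- params
  opt
}
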