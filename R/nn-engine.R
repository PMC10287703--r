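# Minimal neural-network engine (internal): dense and 1-D convolutional
# layers with ReLU, softmax/linear heads, ADAM optimisation and
# reduce-LR-on-plateau scheduling. Written in plain matrix code; the
# architectures used here are small enough that this trains in seconds on a
# single CPU and is exactly reproducible under a fixed seed.

glorot_mat <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# --- dense multilayer perceptron --------------------------------------------

mlp_init <- function(input_dim, widths) {
  dims <- c(input_dim, widths)
  lapply(seq_along(widths), function(i) {
    list(W = glorot_mat(dims[i], dims[i + 1]), b = rep(0, dims[i + 1]))
  })
}

mlp_forward <- function(params, x) {
  nl <- length(params)
  acts <- vector("list", nl + 1)
  zs <- vector("list", nl)
  acts[[1]] <- x
  a <- x
  for (i in seq_len(nl)) {
    z <- a %*% params[[i]]$W +
      matrix(params[[i]]$b, nrow(a), length(params[[i]]$b), byrow = TRUE)
    zs[[i]] <- z
    a <- if (i < nl) pmax(z, 0) else softmax_rows(z)
    acts[[i + 1]] <- a
  }
  list(acts = acts, zs = zs)
}

# gradient of mean categorical cross-entropy wrt all parameters
mlp_backward <- function(params, fw, y_onehot) {
  nl <- length(params)
  n <- nrow(y_onehot)
  grads <- vector("list", nl)
  delta <- (fw$acts[[nl + 1]] - y_onehot) / n
  for (i in nl:1) {
    grads[[i]] <- list(W = crossprod(fw$acts[[i]], delta),
                       b = colSums(delta))
    if (i > 1) delta <- (delta %*% t(params[[i]]$W)) * (fw$zs[[i - 1]] > 0)
  }
  grads
}

cross_entropy <- function(probs, y_onehot) {
  -mean(rowSums(y_onehot * log(probs + 1e-12)))
}

# --- 1-D convolution stack ---------------------------------------------------

conv1d_init <- function(kernel, channels, filters) {
  list(W = array(runif(kernel * channels * filters,
                       -sqrt(6 / (kernel * channels + filters)),
                       sqrt(6 / (kernel * channels + filters))),
                 dim = c(kernel, channels, filters)),
       b = rep(0, filters))
}

# x: array (n, length, channels); valid convolution, stride 1
conv1d_fwd <- function(x, W, b) {
  k <- dim(W)[1]; ch <- dim(W)[2]; f <- dim(W)[3]
  n <- dim(x)[1]; len <- dim(x)[2]
  lout <- len - k + 1
  wm <- matrix(W, k * ch, f)
  out <- array(0, c(n, lout, f))
  for (t in seq_len(lout)) {
    patch <- matrix(x[, t:(t + k - 1), , drop = FALSE], n, k * ch)
    out[, t, ] <- patch %*% wm + matrix(b, n, f, byrow = TRUE)
  }
  out
}

conv1d_bwd <- function(x, W, dout) {
  k <- dim(W)[1]; ch <- dim(W)[2]; f <- dim(W)[3]
  n <- dim(x)[1]; lout <- dim(dout)[2]
  wm <- matrix(W, k * ch, f)
  dx <- array(0, dim(x))
  dW <- array(0, dim(W))
  db <- rep(0, f)
  for (t in seq_len(lout)) {
    dmat <- matrix(dout[, t, ], n, f)
    patch <- matrix(x[, t:(t + k - 1), , drop = FALSE], n, k * ch)
    dW <- dW + array(crossprod(patch, dmat), dim(W))
    db <- db + colSums(dmat)
    dx[, t:(t + k - 1), ] <- dx[, t:(t + k - 1), , drop = FALSE] +
      array(dmat %*% t(wm), c(n, k, ch))
  }
  list(dx = dx, dW = dW, db = db)
}

maxpool1d_fwd <- function(x, pool) {
  n <- dim(x)[1]; len <- dim(x)[2]; f <- dim(x)[3]
  lp <- len %/% pool
  out <- array(-Inf, c(n, lp, f))
  amax <- array(1L, c(n, lp, f))
  for (t in seq_len(lp)) {
    cur <- matrix(out[, t, ], n, f)
    arg <- matrix(amax[, t, ], n, f)
    for (j in seq_len(pool)) {
      v <- matrix(x[, (t - 1) * pool + j, ], n, f)
      sel <- v > cur
      cur[sel] <- v[sel]
      arg[sel] <- j
    }
    out[, t, ] <- cur
    amax[, t, ] <- arg
  }
  list(out = out, amax = amax)
}

maxpool1d_bwd <- function(x, pool, pf, dout) {
  n <- dim(x)[1]; f <- dim(x)[3]
  lp <- dim(pf$out)[2]
  dx <- array(0, dim(x))
  for (t in seq_len(lp)) {
    dmat <- matrix(dout[, t, ], n, f)
    arg <- matrix(pf$amax[, t, ], n, f)
    for (j in seq_len(pool)) {
      mask <- arg == j
      cur <- matrix(dx[, (t - 1) * pool + j, ], n, f)
      cur[mask] <- cur[mask] + dmat[mask]
      dx[, (t - 1) * pool + j, ] <- cur
    }
  }
  dx
}

cnn_init <- function(n_steps, filters, kernel) {
  l1 <- n_steps - kernel + 1
  l2 <- l1 - kernel + 1
  if (l2 < 2) {
    stop("window too short for two convolutions of kernel ", kernel,
         " followed by pooling; increase n_steps", call. = FALSE)
  }
  list(conv1 = conv1d_init(kernel, 1L, filters[1]),
       conv2 = conv1d_init(kernel, filters[1], filters[2]),
       dense = list(W = glorot_mat((l2 %/% 2) * filters[2], 1L),
                    b = 0))
}

cnn_forward <- function(p, x, pool) {
  z1 <- conv1d_fwd(x, p$conv1$W, p$conv1$b)
  a1 <- pmax(z1, 0)
  z2 <- conv1d_fwd(a1, p$conv2$W, p$conv2$b)
  a2 <- pmax(z2, 0)
  pf <- maxpool1d_fwd(a2, pool)
  n <- dim(x)[1]
  flat <- matrix(pf$out, n, length(pf$out) / n)
  yhat <- drop(flat %*% p$dense$W + p$dense$b)
  list(z1 = z1, a1 = a1, z2 = z2, a2 = a2, pf = pf, flat = flat,
       yhat = yhat)
}

cnn_backward <- function(p, fw, x, y, pool) {
  n <- dim(x)[1]
  dyhat <- matrix(2 * (fw$yhat - y) / n, n, 1)
  dW_dense <- crossprod(fw$flat, dyhat)
  db_dense <- sum(dyhat)
  dflat <- dyhat %*% t(p$dense$W)
  dpool <- array(dflat, dim(fw$pf$out))
  da2 <- maxpool1d_bwd(fw$a2, pool, fw$pf, dpool)
  dz2 <- da2 * (fw$z2 > 0)
  g2 <- conv1d_bwd(fw$a1, p$conv2$W, dz2)
  dz1 <- g2$dx * (fw$z1 > 0)
  g1 <- conv1d_bwd(x, p$conv1$W, dz1)
  list(conv1 = list(W = g1$dW, b = g1$db),
       conv2 = list(W = g2$dW, b = g2$db),
       dense = list(W = dW_dense, b = db_dense))
}

# --- ADAM over an arbitrary nested parameter list ---------------------------

adam_state <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  corr1 <- 1 - beta1^st$t
  corr2 <- 1 - beta2^st$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, st$m, st$v)
  st$m <- r$m
  st$v <- r$v
  list(params = r$p, state = st)
}

# reduce-on-plateau learning-rate schedule: halve after `patience` epochs
# without improvement, never below min_lr
plateau_update <- function(sched, loss) {
  if (loss < sched$best - 1e-12) {
    sched$best <- loss
    sched$wait <- 0L
  } else {
    sched$wait <- sched$wait + 1L
    if (sched$wait >= sched$patience) {
      sched$lr <- max(sched$lr * sched$factor, sched$min_lr)
      sched$wait <- 0L
    }
  }
  sched
}

# min-max scaling to [0, 1]; a constant column maps to 0.5 so the inverse
# recovers the constant
minmax_fit <- function(x) {
  x <- as.matrix(x)
  list(min = apply(x, 2, min), max = apply(x, 2, max))
}

minmax_apply <- function(sc, x) {
  x <- as.matrix(x)
  rng <- sc$max - sc$min
  out <- sweep(x, 2, sc$min)
  for (j in seq_along(rng)) {
    out[, j] <- if (rng[j] > 0) out[, j] / rng[j] else 0.5
  }
  out
}

minmax_invert <- function(sc, x) {
  x <- as.matrix(x)
  rng <- sc$max - sc$min
  for (j in seq_along(rng)) {
    x[, j] <- if (rng[j] > 0) x[, j] * rng[j] + sc$min[j] else sc$min[j]
  }
  x
}
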