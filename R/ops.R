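# Differentiable array operations. Each op accepts `ag_node`s or plain
# numeric arrays, computes forward with compiled kernels or vectorized R,
# and registers a backward closure on the tape when recording.
#
# Feature maps are [H, W, C, N]; feature matrices are [D, N] (one column per
# image), so a batch flows through linear layers as W %*% x.

op_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  xv <- ag_value(x); wv <- ag_value(w); bv <- ag_value(b)
  y <- conv2d_fwd_cpp(xv, wv, bv, as.integer(stride), as.integer(pad))
  ag_node(y, backward = function(node) {
    gr <- conv2d_bwd_cpp(xv, wv, node$grad, as.integer(stride), as.integer(pad))
    ag_accum(x, gr$dx); ag_accum(w, gr$dw); ag_accum(b, gr$db)
  })
}

op_relu <- function(x) {
  xv <- ag_value(x)
  y <- pmax(xv, 0)
  if (!is.null(dim(xv))) dim(y) <- dim(xv)
  ag_node(y, backward = function(node) {
    g <- node$grad * (xv > 0)
    ag_accum(x, g)
  })
}

op_add <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_node(av + bv, backward = function(node) {
    ag_accum(a, node$grad); ag_accum(b, node$grad)
  })
}

op_maxpool <- function(x, k, stride, pad = 0L) {
  xv <- ag_value(x)
  r <- maxpool_fwd_cpp(xv, as.integer(k), as.integer(stride), as.integer(pad))
  xd <- dim(xv)
  ag_node(r$y, backward = function(node) {
    ag_accum(x, maxpool_bwd_cpp(node$grad, r$idx, as.integer(xd)))
  })
}

# Global average pooling [H,W,C,N] -> [C,N]
op_gap <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv); P <- d[1] * d[2]
  y <- matrix(.colMeans(xv, P, d[3] * d[4]), d[3], d[4])
  ag_node(y, backward = function(node) {
    g <- array(rep(as.vector(node$grad) / P, each = P), dim = d)
    ag_accum(x, g)
  })
}

# Global max pooling [H,W,C,N] -> [C,N]; first-occurrence argmax ties
op_gmp <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv); P <- d[1] * d[2]
  m <- matrix(xv, P, d[3] * d[4])
  idx <- max.col(t(m), ties.method = "first")
  cols <- seq_len(ncol(m))
  y <- matrix(m[cbind(idx, cols)], d[3], d[4])
  ag_node(y, backward = function(node) {
    g <- numeric(length(xv))
    g[(cols - 1L) * P + idx] <- as.vector(node$grad)
    dim(g) <- d
    ag_accum(x, g)
  })
}

# Horizontal band x[h0:h1, , , ] of a feature map (stripe partition)
op_slice_h <- function(x, h0, h1) {
  xv <- ag_value(x)
  d <- dim(xv)
  y <- xv[h0:h1, , , , drop = FALSE]
  ag_node(y, backward = function(node) {
    g <- array(0, dim = d)
    g[h0:h1, , , ] <- node$grad
    ag_accum(x, g)
  })
}

# Vertical band x[, w0:w1, , ] of a feature map
op_slice_w <- function(x, w0, w1) {
  xv <- ag_value(x)
  d <- dim(xv)
  y <- xv[, w0:w1, , , drop = FALSE]
  ag_node(y, backward = function(node) {
    g <- array(0, dim = d)
    g[, w0:w1, , ] <- node$grad
    ag_accum(x, g)
  })
}

# Row block of a feature matrix [D,N]
op_rows <- function(x, i0, i1) {
  xv <- ag_value(x)
  d <- dim(xv)
  y <- xv[i0:i1, , drop = FALSE]
  ag_node(y, backward = function(node) {
    g <- matrix(0, d[1], d[2])
    g[i0:i1, ] <- node$grad
    ag_accum(x, g)
  })
}

# Row-wise concatenation of feature matrices [D_i, N] -> [sum D_i, N]
op_concat_rows <- function(xs) {
  vals <- lapply(xs, ag_value)
  drows <- vapply(vals, nrow, 1L)
  y <- do.call(rbind, vals)
  offs <- cumsum(c(0L, drows))
  ag_node(y, backward = function(node) {
    for (i in seq_along(xs)) {
      ag_accum(xs[[i]], node$grad[(offs[i] + 1L):offs[i + 1L], , drop = FALSE])
    }
  })
}

op_linear <- function(x, w, b) {
  xv <- ag_value(x); wv <- ag_value(w); bv <- ag_value(b)
  y <- wv %*% xv + bv
  ag_node(y, backward = function(node) {
    g <- node$grad
    ag_accum(w, g %*% t(xv))
    ag_accum(x, crossprod(wv, g))
    ag_accum(b, rowSums(g))
  })
}

# Per-channel statistics of [H,W,C,N] as a C-vector
.chan_stat <- function(x, d, fun) {
  P <- d[1] * d[2]
  rowMeans(matrix(fun(matrix(x, P, d[3] * d[4])), d[3], d[4]))
}

# Batch normalization over a [H,W,C,N] map (per channel) or a [D,N] matrix
# (per feature). `state` is an environment carrying running_mean/running_var,
# updated in place during training with exponential moving average `momentum`.
op_batchnorm <- function(x, gamma, beta, state, training, eps = 1e-5,
                         momentum = 0.1) {
  xv <- ag_value(x)
  gv <- ag_value(gamma); bv <- ag_value(beta)
  d <- dim(xv)
  map4 <- length(d) == 4L
  P <- if (map4) d[1] * d[2] else 1L
  C <- if (map4) d[3] else d[1]
  Nrep <- if (map4) d[4] else d[2]
  m <- P * Nrep
  if (training) {
    if (map4) {
      mu <- .chan_stat(xv, d, colMeans)
      ex2 <- .chan_stat(xv * xv, d, colMeans)
    } else {
      mu <- rowMeans(xv)
      ex2 <- rowMeans(xv * xv)
    }
    varb <- pmax(ex2 - mu^2, 0)
    unb <- if (m > 1) m / (m - 1) else 1
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * varb * unb
  } else {
    mu <- state$running_mean
    varb <- state$running_var
  }
  inv_sd <- 1 / sqrt(varb + eps)
  expand <- function(v) if (map4) rep(v, each = P) else v
  xhat <- (xv - expand(mu)) * expand(inv_sd)
  y <- xhat * expand(gv) + expand(bv)
  if (!is.null(d)) dim(y) <- d
  ag_node(y, backward = function(node) {
    dy <- node$grad
    sum_c <- function(a) {
      if (map4) {
        rowSums(matrix(colSums(matrix(a, P, C * Nrep)), C, Nrep))
      } else rowSums(a)
    }
    ag_accum(gamma, sum_c(dy * xhat))
    ag_accum(beta, sum_c(dy))
    dxhat <- dy * expand(gv)
    if (training) {
      s1 <- sum_c(dxhat)
      s2 <- sum_c(dxhat * xhat)
      dx <- expand(inv_sd / m) * (m * dxhat - expand(s1) - xhat * expand(s2))
    } else {
      dx <- dxhat * expand(inv_sd)
    }
    if (!is.null(d)) dim(dx) <- d
    ag_accum(x, dx)
  })
}

# Bilinear sampling of a feature map under per-image scale+shift affine
# parameters theta [4,N] = rows (sx, sy, tx, ty); zero padding, align-corners.
op_grid_sample <- function(x, theta, out_h, out_w) {
  xv <- ag_value(x); tv <- ag_value(theta)
  if (out_h < 1 || out_w < 1) stop("sample_region: output grid must be at least 1x1")
  y <- grid_sample_fwd_cpp(xv, tv, as.integer(out_h), as.integer(out_w))
  ag_node(y, backward = function(node) {
    gr <- grid_sample_bwd_cpp(xv, tv, node$grad)
    ag_accum(x, gr$dx)
    ag_accum(theta, gr$dtheta)
  })
}

# Weighted sum of scalar loss nodes: sum(weights[i] * terms[[i]])
op_scalar_lincomb <- function(terms, weights) {
  vals <- vapply(terms, function(t) as.numeric(ag_value(t)), 0)
  ag_node(sum(weights * vals), backward = function(node) {
    for (i in seq_along(terms)) ag_accum(terms[[i]], weights[i] * node$grad)
  })
}
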