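# Shared fixtures and oracles. Synthetic datasets are generated once per
# test session (they are deterministic in their seeds) and reused.

.fixture_cache <- new.env(parent = emptyenv())

synth_fixture <- function(name = c("small", "desk", "mini")) {
  name <- match.arg(name)
  if (!is.null(.fixture_cache[[name]])) return(.fixture_cache[[name]])
  dir <- file.path(tempdir(), paste0("cowreid-fixture-", name))
  if (!dir.exists(dir)) {
    switch(name,
      # small: quick unit-test dataset
      small = generate_dataset(dir, num_train_ids = 10, num_test_ids = 5,
                               imgs_per_train_id = 10, query_per_id = 5,
                               gallery_per_id = 8, image_size = c(64, 32),
                               global_seed = 11),
      # mini: smallest viable layout for CLI round trips
      mini = generate_dataset(dir, num_train_ids = 8, num_test_ids = 3,
                              imgs_per_train_id = 4, query_per_id = 2,
                              gallery_per_id = 3, image_size = c(48, 24),
                              global_seed = 3),
      # desk: the study-scale conditions (20 train identities x 50 images,
      # 10 test identities with 10 query + 20 gallery each, 96x48 images)
      desk = generate_dataset(dir, num_train_ids = 20, num_test_ids = 10,
                              imgs_per_train_id = 50, query_per_id = 10,
                              gallery_per_id = 20, image_size = c(96, 48),
                              global_seed = 7))
  }
  .fixture_cache[[name]] <- dir
  dir
}

# Central-difference numeric gradient of scalar f at sampled entries of x
fd_grad_at <- function(f, x, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, 0)
}

expect_grad_matches <- function(f, x, analytic, n = 10, tol = 1e-5) {
  idx <- sample(length(x), min(n, length(x)))
  num <- fd_grad_at(f, x, idx)
  expect_lt(max(abs(num - analytic[idx]) / pmax(1, abs(num))), tol)
}

# Independent bilinear reference for scale+shift sampling (zero padding,
# align-corners), written against the coordinate definition directly
ref_grid_sample <- function(x, theta, out_h, out_w) {
  d <- dim(x)
  y <- array(0, dim = c(out_h, out_w, d[3], d[4]))
  nc <- function(i, n) if (n > 1) -1 + 2 * (i - 1) / (n - 1) else 0
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    for (wo in seq_len(out_w)) for (ho in seq_len(out_h)) {
      xs <- theta[1, n] * nc(wo, out_w) + theta[3, n]
      ys <- theta[2, n] * nc(ho, out_h) + theta[4, n]
      u <- (xs + 1) * (d[2] - 1) / 2 + 1
      v <- (ys + 1) * (d[1] - 1) / 2 + 1
      u0 <- floor(u); v0 <- floor(v)
      acc <- 0
      for (dj in 0:1) for (di in 0:1) {
        uu <- u0 + dj; vv <- v0 + di
        if (uu >= 1 && uu <= d[2] && vv >= 1 && vv <= d[1]) {
          wu <- if (dj == 1) u - u0 else 1 - (u - u0)
          wv <- if (di == 1) v - v0 else 1 - (v - v0)
          acc <- acc + wu * wv * x[vv, uu, c, n]
        }
      }
      y[ho, wo, c, n] <- acc
    }
  }
  y
}

# Brute-force constraint-loss evaluator for one image's module quadruples
# (rows sx, sy, tx, ty are columns of an M x 4 matrix), written directly
# from the definitions
ref_constraints <- function(q, alpha = 0.5, beta = 0.1, gamma = 0.71,
                            delta = 0.4, lambda1 = 0.1, lambda2 = 0.1) {
  M <- nrow(q)
  l_ss <- 0; l_sp <- 0; l_ts <- 0; l_te <- 0
  for (m in seq_len(M)) {
    l_ss <- l_ss + max(abs(q[m, 1]) - alpha, 0)^2 + max(abs(q[m, 2]) - alpha, 0)^2
    l_sp <- l_sp + max(0, beta - q[m, 1]) + max(0, beta - q[m, 2])
    l_ts <- l_ts + max(abs(q[m, 3]) - gamma, 0)^2 + max(abs(q[m, 4]) - gamma, 0)^2
  }
  if (M >= 2) {
    for (i in 1:(M - 1)) for (j in (i + 1):M) {
      d2 <- (q[i, 3] - q[j, 3])^2 + (q[i, 4] - q[j, 4])^2
      l_te <- l_te + max(0, delta - d2)
    }
  }
  c(L_SS = l_ss, L_SP = l_sp, L_TS = l_ts, L_TE = l_te,
    L_STN = l_ss + lambda1 * l_sp + l_ts + lambda2 * l_te)
}

# Exhaustive reference ranking evaluator (precision-at-hit AP, explicit
# stable sort), independent of the package's vectorized implementations
ref_eval <- function(sim, qids, gids, ks = c(1, 5, 10)) {
  ap <- numeric(length(qids))
  hits <- matrix(FALSE, length(qids), length(ks))
  for (i in seq_along(qids)) {
    ord <- sort.list(-sim[i, ], method = "radix")
    rel <- gids[ord] == qids[i]
    prec_at_hits <- vapply(which(rel), function(p) sum(rel[1:p]) / p, 0)
    ap[i] <- mean(prec_at_hits)
    for (j in seq_along(ks)) {
      k <- min(ks[j], length(gids))
      hits[i, j] <- any(rel[1:k])
    }
  }
  list(map = mean(ap), ap = ap, rank = colMeans(hits))
}
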