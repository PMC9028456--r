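# Training objectives: triplet loss against an exhaustive pair oracle,
# smoothed cross-entropy against closed forms, and the joint loss assemblies
# with their component censuses.

ag_value <- cowreid:::ag_value
ag_no_grad <- cowreid:::ag_no_grad

test_that("triplet loss handles the satisfied and worst-case margins", {
  # two points per identity, controlled distances
  f <- matrix(0, 2, 4)
  f[, 3] <- c(1, 0); f[, 4] <- c(1, 0)   # id B at distance 1 from id A
  labs <- c(0, 0, 1, 1)
  # D(a,p)^2 = 0, D(a,n)^2 = 1, margin 0.3: hinge max(0, -0.7) = 0
  expect_equal(triplet_loss(f, labs, triplet_config(margin = 0.3)), 0)
  # collapse everything: D(a,p)^2 = D(a,n)^2 = 0 -> every anchor pays margin
  f0 <- matrix(0, 2, 4)
  expect_equal(triplet_loss(f0, labs, triplet_config(margin = 0.3)), 0.3)
  # positives at distance 1, negatives at 0: term = 1 + margin
  f2 <- rbind(c(0, 1, 0, 1), c(0, 0, 0, 0))
  expect_equal(triplet_loss(f2, labs, triplet_config(margin = 0.3)), 1.3)
})

test_that("batch-hard mining equals a brute-force min/max pair oracle", {
  set.seed(41)
  for (rep in 1:20) {
    f <- matrix(stats::rnorm(3 * 8), 3, 8)
    labs <- sample(rep(1:2, each = 4))
    got <- triplet_loss(f, labs, triplet_config(margin = 0.5))
    d2 <- as.matrix(stats::dist(t(f)))^2
    terms <- vapply(1:8, function(i) {
      pos <- setdiff(which(labs == labs[i]), i)
      dp <- max(d2[i, pos])
      dn <- min(d2[i, labs != labs[i]])
      max(0, dp - dn + 0.5)
    }, 0)
    expect_equal(got, mean(terms), tolerance = 1e-10)
  }
})

test_that("all-valid mining averages every triplet and scales quadratically", {
  set.seed(42)
  f <- matrix(stats::rnorm(2 * 6), 2, 6)
  labs <- rep(1:3, each = 2)
  cfg <- triplet_config(margin = 50, mining = "all_valid")  # all terms active
  base <- triplet_loss(f, labs, cfg)
  # oracle: loop over all anchor/positive/negative triples
  d2 <- as.matrix(stats::dist(t(f)))^2
  acc <- c()
  for (i in 1:6) for (p in which(labs == labs[i])) for (n in which(labs != labs[i])) {
    if (p != i) acc <- c(acc, max(0, d2[i, p] - d2[i, n] + 50))
  }
  expect_equal(base, mean(acc), tolerance = 1e-10)
  # translation invariance and c^2 scaling of the distance part
  shift <- triplet_loss(f + 3, labs, cfg)
  expect_equal(base, shift, tolerance = 1e-10)
  scaled <- triplet_loss(2 * f, labs, cfg)
  expect_equal(scaled - 50, 4 * (base - 50), tolerance = 1e-8)
})

test_that("degenerate batches are rejected with sampler advice", {
  f <- matrix(stats::rnorm(4), 2, 2)
  expect_error(triplet_loss(f, c(1, 2)), "PK sampler")
  expect_error(triplet_loss(f, c(1, 1)), "PK sampler")
})

test_that("label smoothing reduces to plain cross-entropy at epsilon 0", {
  set.seed(43)
  lg <- matrix(stats::rnorm(6 * 5), 6, 5)
  labs <- c(0, 2, 5, 1, 3)
  got <- label_smooth_ce(lg, labs, smoothing_config(0))
  p <- apply(lg, 2, function(c) exp(c - max(c)) / sum(exp(c - max(c))))
  expect_equal(got, -mean(log(p[cbind(labs + 1, 1:5)])), tolerance = 1e-10)
})

test_that("the smoothed target puts 1-(N-1)eps/N on the label and sums to 1", {
  # N = 10, eps = 0.1: q_y = 0.91, q_other = 0.01
  lg <- matrix(0, 10, 1); lg[3, 1] <- 5
  labs <- 2L
  eps <- 0.1
  qy <- 1 - 9 * 0.1 / 10
  expect_equal(qy, 0.91)
  lsm <- lg[, 1] - (max(lg) + log(sum(exp(lg - max(lg)))))
  manual <- -(qy * lsm[3] + sum(0.01 * lsm[-3]))
  expect_equal(label_smooth_ce(lg, labs, smoothing_config(eps)), manual,
               tolerance = 1e-12)
  # uniform logits cost log N for any target summing to one
  for (eps in c(0, 0.1, 0.4)) {
    expect_equal(label_smooth_ce(matrix(2, 7, 3), c(0, 3, 6),
                                 smoothing_config(eps)),
                 log(7), tolerance = 1e-12)
  }
  expect_error(label_smooth_ce(matrix(0, 4, 1), 4L), "labels")
})

test_that("smoothed CE is bounded below by the target entropy (Gibbs)", {
  eps <- 0.2; ncls <- 5
  q <- rep(eps / ncls, ncls); q[2] <- 1 - (ncls - 1) * eps / ncls
  hq <- -sum(q * log(q))
  # optimal logits are log q (softmax = q): loss attains the entropy
  expect_equal(label_smooth_ce(matrix(log(q), ncls, 1), 1L,
                               smoothing_config(eps)),
               hq, tolerance = 1e-10)
  set.seed(44)
  for (rep in 1:20) {
    lg <- matrix(stats::rnorm(ncls), ncls, 1)
    expect_gte(label_smooth_ce(lg, 1L, smoothing_config(eps)), hq - 1e-12)
  }
})

test_that("the GPN joint loss exposes 6 triplet + 8 classification terms", {
  set.seed(45)
  m <- build_model(model_config("tiny", "gpn", num_classes = 4))
  x <- array(stats::rnorm(96 * 48 * 3 * 8), c(96, 48, 3, 8))
  labs <- rep(0:3, each = 2)
  out <- ag_no_grad(forward_train(m, x, training = TRUE))
  lo <- gpn_total_loss(out, labs)
  expect_length(lo$components, 14)
  expect_equal(sum(startsWith(names(lo$components), "triplet_")), 6)
  expect_equal(sum(startsWith(names(lo$components), "ce_")), 8)
  expect_true(all(lo$components >= 0))
  # the total equals the independently assembled sum of components / divisors
  tri <- lo$components[startsWith(names(lo$components), "triplet_")]
  ce <- lo$components[startsWith(names(lo$components), "ce_")]
  expect_equal(as.numeric(ag_value(lo$total)), sum(tri) / 6 + sum(ce) / 8,
               tolerance = 1e-6)
  expect_error(gpn_total_loss(out[setdiff(names(out), "P_Avg")], labs),
               "missing branch outputs")
})

test_that("collapsed features and uniform logits give the closed-form loss", {
  # all features at one point -> each triplet term is the margin; uniform
  # logits -> each classification term is log N
  ncls <- 5; n <- 8
  labs <- rep(0:3, each = 2)
  feat0 <- function(d) matrix(0, d, n)
  logit0 <- function() matrix(0, ncls, n)
  outputs <- list(G_Avg = feat0(6), G_Max = feat0(6), M_Avg = feat0(3),
                  M_Max = feat0(3), P_Avg = feat0(12), P_Max = feat0(12),
                  G_logits = logit0(), M_logits = logit0(),
                  P_logits = replicate(6, logit0(), simplify = FALSE))
  lo <- gpn_total_loss(outputs, labs, triplet_config(margin = 0.3))
  expect_equal(as.numeric(lo$total), 0.3 + log(ncls), tolerance = 1e-12)
  # doubling every logit matrix leaves uniform logits uniform; instead check
  # linearity of the classification block via epsilon = 0 vs manual sum
  ce <- lo$components[startsWith(names(lo$components), "ce_")]
  expect_equal(unname(ce), rep(log(ncls), 8), tolerance = 1e-12)
})

test_that("the GPN-ST joint loss has divisors 4 and 6 plus the STN term", {
  set.seed(46)
  m <- build_model(model_config("tiny", "gpn_st", num_classes = 4))
  x <- array(stats::rnorm(96 * 48 * 3 * 8), c(96, 48, 3, 8))
  labs <- rep(0:3, each = 2)
  out <- ag_no_grad(forward_train_st(m, x, training = TRUE))
  lo <- gpnst_total_loss(out, labs)
  expect_length(lo$components, 15)  # 4 triplet + 6 ce + 5 constraint entries
  expect_equal(sum(startsWith(names(lo$components), "triplet_")), 4)
  expect_equal(sum(startsWith(names(lo$components), "ce_")), 6)
  expect_true(all(c("L_SS", "L_SP", "L_TS", "L_TE", "L_STN") %in%
                  names(lo$components)))
  tri <- lo$components[startsWith(names(lo$components), "triplet_")]
  ce <- lo$components[startsWith(names(lo$components), "ce_")]
  expect_equal(as.numeric(ag_value(lo$total)),
               sum(tri) / 4 + sum(ce) / 6 + lo$components[["L_STN"]],
               tolerance = 1e-6)
  # L_STN matches the stn module's own evaluation of the same parameters
  th <- ag_value(out$theta)
  con <- constraint_losses(th, n_modules = 4)
  expect_equal(lo$components[["L_STN"]], con$L_STN, tolerance = 1e-10)
  # warm-start centers (+-0.3, +-0.3) sit 0.36 < delta = 0.4 apart on the
  # four adjacent pairs, so the exclusion term starts mildly active:
  # L_TE = 4 * (0.4 - 0.36) = 0.16, L_STN = lambda2 * L_TE = 0.016
  expect_equal(lo$components[["L_TE"]], 0.16, tolerance = 1e-10)
  expect_equal(lo$components[["L_STN"]], 0.016, tolerance = 1e-10)
})
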