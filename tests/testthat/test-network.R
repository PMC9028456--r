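# The multi-branch forward pass: dimensionality contracts, the stripe
# partition against an independent pooling oracle, dual-pooling identities,
# embedding assembly order and determinism.

ag_value <- cowreid:::ag_value
ag_no_grad <- cowreid:::ag_no_grad

tiny_gpn <- function(num_classes = 4, ...) {
  set.seed(77)
  build_model(model_config("tiny", "gpn", num_classes = num_classes, ...))
}

test_that("tiny backbone honors the two-map contract", {
  m <- tiny_gpn()
  x <- array(stats::rnorm(96 * 48 * 3 * 2), c(96, 48, 3, 2))
  maps <- ag_no_grad(cowreid:::backbone_forward(m, x, training = FALSE))
  dm <- dim(ag_value(maps$mid)); dh <- dim(ag_value(maps$high))
  expect_equal(dm[1:2], dh[1:2])  # stride-1 final stage
  expect_equal(dm[3], m$config$channels$mid)
  expect_equal(dh[3], m$config$channels$high)
})

test_that("forward pass produces the scaled branch dimensions and 8 heads", {
  m <- tiny_gpn(num_classes = 11)
  x <- array(stats::rnorm(96 * 48 * 3 * 3), c(96, 48, 3, 3))
  out <- ag_no_grad(forward_train(m, x, training = FALSE))
  ch <- m$config$channels
  expect_equal(nrow(ag_value(out$G)), ch$high)
  expect_equal(nrow(ag_value(out$M)), ch$mid)
  expect_equal(nrow(ag_value(out$P_Avg)), 6 * ch$high)
  expect_length(out$P_stripe, 6)
  expect_equal(nrow(ag_value(out$P_stripe[[1]])), ch$high)
  logits <- c(list(out$G_logits, out$M_logits), out$P_logits)
  expect_length(logits, 8)
  for (lg in logits) expect_equal(dim(ag_value(lg)), c(11L, 3L))
  for (f in c(list(out$G_Down, out$M_Down), out$P_Down)) {
    expect_equal(nrow(ag_value(f)), m$config$feat_dim)
  }
})

test_that("additive pooling identities hold: G = G_Avg + G_Max, P likewise", {
  m <- tiny_gpn()
  x <- array(stats::rnorm(96 * 48 * 3 * 2), c(96, 48, 3, 2))
  out <- ag_no_grad(forward_train(m, x, training = FALSE))
  expect_equal(ag_value(out$G), ag_value(out$G_Avg) + ag_value(out$G_Max))
  expect_equal(ag_value(out$M), ag_value(out$M_Avg) + ag_value(out$M_Max))
  expect_equal(ag_value(out$P), ag_value(out$P_Avg) + ag_value(out$P_Max))
})

test_that("stripe pooling equals an independent array-slicing oracle", {
  m <- tiny_gpn()
  x <- array(stats::rnorm(96 * 48 * 3 * 2), c(96, 48, 3, 2))
  maps <- ag_no_grad(cowreid:::backbone_forward(m, x, training = FALSE))
  high <- ag_value(maps$high)
  out <- ag_no_grad(forward_train(m, x, training = FALSE))
  H <- dim(high)[1]
  cuts <- round(seq(0, H, length.out = 7))
  oracle <- do.call(rbind, lapply(1:6, function(k) {
    band <- high[(cuts[k] + 1):cuts[k + 1], , , , drop = FALSE]
    d <- dim(band)
    flat <- matrix(band, d[1] * d[2], d[3] * d[4])
    matrix(colMeans(flat) + apply(flat, 2, max), d[3], d[4])
  }))
  expect_lt(max(abs(oracle - ag_value(out$P))), 1e-5)
  # stripes tile the map: area-weighted stripe means equal the global mean
  stripe_means <- lapply(1:6, function(k) {
    band <- high[(cuts[k] + 1):cuts[k + 1], , , , drop = FALSE]
    d <- dim(band)
    list(w = d[1], m = matrix(colMeans(matrix(band, d[1] * d[2], d[3] * d[4])),
                              d[3], d[4]))
  })
  w <- vapply(stripe_means, `[[`, 0, "w")
  weighted <- Reduce(`+`, Map(function(s) s$w * s$m, stripe_means)) / sum(w)
  expect_lt(max(abs(weighted - ag_value(out$G_Avg))), 1e-5)
})

test_that("average and max pooling coincide on spatially constant maps", {
  x <- array(rep(stats::rnorm(5 * 2), each = 8 * 4), c(8, 4, 5, 2))
  a <- ag_value(cowreid:::op_gap(x))
  m <- ag_value(cowreid:::op_gmp(x))
  expect_equal(a, m, tolerance = 1e-12)
  g <- ag_value(cowreid:::op_add(cowreid:::op_gap(x), cowreid:::op_gmp(x)))
  expect_equal(g, 2 * a, tolerance = 1e-12)
})

test_that("zero input yields zero pooled vectors (bias-free path)", {
  m <- tiny_gpn()
  x <- array(0, c(96, 48, 3, 2))
  out <- ag_no_grad(forward_train(m, x, training = FALSE))
  expect_equal(max(abs(ag_value(out$G))), 0)
  expect_equal(max(abs(ag_value(out$M))), 0)
  expect_equal(max(abs(ag_value(out$P))), 0)
})

test_that("embeddings are deterministic and ordered [G, M, P1..P6]", {
  m <- tiny_gpn()
  x <- array(stats::rnorm(96 * 48 * 3 * 2), c(96, 48, 3, 2))
  e1 <- embed_images(m, x)
  e2 <- embed_images(m, x)
  expect_identical(e1, e2)
  expect_equal(ncol(e1), embedding_dim(m))
  expect_equal(embedding_dim(m), 8 * m$config$feat_dim)
  # boundary markers: force each head to a constant = its position
  fd <- m$config$feat_dim
  layout <- embedding_layout(m)
  for (i in seq_len(nrow(layout))) {
    h <- layout$head[i]
    m$params[[paste0("head_", h, ".reduce.w")]]$value[] <- 0
    m$params[[paste0("head_", h, ".reduce.b")]]$value[] <- 0
    m$params[[paste0("head_", h, ".bn.gamma")]]$value[] <- 0
    m$params[[paste0("head_", h, ".bn.beta")]]$value[] <- i
  }
  e <- embed_images(m, x)
  for (i in seq_len(nrow(layout))) {
    seg <- e[, layout$from[i]:layout$to[i]]
    expect_true(all(abs(seg - i) < 1e-8))
  }
})

test_that("small inputs that cannot form six stripes are rejected clearly", {
  m <- tiny_gpn(input_size = c(32, 48))
  x <- array(stats::rnorm(32 * 48 * 3), c(32, 48, 3, 1))
  expect_error(ag_no_grad(forward_train(m, x, training = FALSE)),
               "at least 6")
})

test_that("pretrained weights are refused with advice", {
  expect_error(model_config("resnet50", "gpn", num_classes = 5,
                            pretrained = TRUE),
               "pretrained = FALSE")
})

test_that("classifier width follows the number of training identities", {
  m <- tiny_gpn(num_classes = 200)
  x <- array(stats::rnorm(96 * 48 * 3), c(96, 48, 3, 1))
  out <- ag_no_grad(forward_train(m, x, training = FALSE))
  expect_equal(nrow(ag_value(out$G_logits)), 200L)
  expect_equal(nrow(ag_value(out$P_logits[[6]])), 200L)
})
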