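# The attention Part branch: localization warm start, region sampling
# against the coordinate definition, the four constraint losses against a
# brute-force evaluator, and the GPN-ST forward contract.

ag_value <- cowreid:::ag_value
ag_no_grad <- cowreid:::ag_no_grad

tiny_st <- function(num_classes = 4, ...) {
  set.seed(78)
  build_model(model_config("tiny", "gpn_st", num_classes = num_classes, ...))
}

test_that("zero-weight localization nets emit their warm-start quadruples", {
  m <- tiny_st()
  x <- array(stats::rnorm(96 * 48 * 3 * 3), c(96, 48, 3, 3))
  maps <- ag_no_grad(cowreid:::backbone_forward(m, x, training = FALSE))
  th <- ag_value(ag_no_grad(localize(m, maps$high)))
  expect_equal(dim(th), c(16L, 3L))
  arr <- array(th, c(4, 4, 3))
  for (mm in 1:4) for (n in 1:3) {
    expect_equal(arr[, mm, n], cowreid:::stn_init_quadruple(mm),
                 tolerance = 1e-12)
  }
  # pairwise squared center distances at the warm start: 0.36 (adjacent) or
  # 0.72 (diagonal)
  centers <- t(arr[3:4, , 1])
  d2 <- as.vector(stats::dist(centers))^2
  expect_true(all(abs(d2 - 0.36) < 1e-9 | abs(d2 - 0.72) < 1e-9))
})

test_that("region sampling matches direct coordinate interpolation", {
  set.seed(6)
  x <- array(stats::rnorm(8 * 6 * 3 * 2), c(8, 6, 3, 2))
  th <- matrix(c(0.5, 0.5, 0.2, -0.1, 0.3, 0.6, -0.4, 0.3), 4, 2)
  got <- ag_value(sample_region(x, th, c(5, 4)))
  expect_equal(as.vector(got), as.vector(ref_grid_sample(x, th, 5, 4)),
               tolerance = 1e-10)
  # identity parameters at the source size reproduce the map
  id <- ag_value(sample_region(x, c(1, 1, 0, 0), c(8, 6)))
  expect_lt(max(abs(id - x)), 1e-5)
  # halving the scale magnifies the center: a central hot spot stays central
  hot <- array(0, c(9, 9, 1, 1)); hot[5, 5, 1, 1] <- 1
  mag <- ag_value(sample_region(hot, c(0.5, 0.5, 0, 0), c(9, 9)))
  expect_equal(which.max(mag), which.max(hot))
  expect_gt(sum(mag), sum(hot))  # the spot now covers more output area
  # far out-of-range translation lands almost entirely in zero padding
  far <- ag_value(sample_region(x, c(0.5, 0.5, 2, 0), c(6, 6)))
  expect_gt(mean(far == 0), 0.9)
  expect_error(sample_region(x, th, c(0, 4)), "out_hw")
})

test_that("constraint losses match the brute-force evaluator on a grid", {
  vals <- c(-0.9, -0.6, -0.2, 0.05, 0.12, 0.3, 0.5, 0.72, 0.9)
  set.seed(13)
  for (rep in 1:60) {
    q <- matrix(sample(vals, 16, replace = TRUE), 4, 4)
    got <- constraint_losses(q)
    want <- ref_constraints(q)
    for (nm in names(want)) expect_equal(got[[nm]], unname(want[nm]),
                                         tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("constraint losses vanish exactly on the feasible set", {
  # the worked feasible configuration: scales 0.3, centers (+-0.35, +-0.35)
  q <- cbind(0.3, 0.3, c(-0.35, 0.35, -0.35, 0.35), c(-0.35, -0.35, 0.35, 0.35))
  got <- constraint_losses(q)
  expect_equal(got$L_SS, 0); expect_equal(got$L_SP, 0)
  expect_equal(got$L_TS, 0); expect_equal(got$L_TE, 0)
  expect_equal(got$L_STN, 0)
  # single out-of-range scale contributes (0.7 - 0.5)^2 = 0.04
  q2 <- q; q2[1, 1] <- 0.7; q2[1, 2] <- 0.3
  expect_equal(constraint_losses(q2)$L_SS, 0.04)
  # coincident centers contribute delta = 0.4 per pair
  q3 <- q; q3[2, 3:4] <- q3[1, 3:4]
  expect_equal(constraint_losses(q3)$L_TE, 0.4)
  # one module only: L_TE degenerates to zero with a warning
  expect_warning(one <- constraint_losses(q[1, , drop = FALSE]), "L_TE")
  expect_equal(one$L_TE, 0)
})

test_that("constraint subgradients push parameters back into range", {
  grad_of <- function(q) {
    tn <- cowreid:::ag_param(matrix(t(q), 16, 1))
    cowreid:::ag_record({
      cl <- constraint_losses(tn)
      cowreid:::ag_backward(cl$L_STN)
    })
    matrix(tn$grad, 4)  # rows sx, sy, tx, ty; cols modules
  }
  feasible <- cbind(0.3, 0.3, c(-0.35, 0.35, -0.35, 0.35),
                    c(-0.35, -0.35, 0.35, 0.35))
  big <- feasible; big[1, 1] <- 0.8          # sx above alpha
  expect_gt(grad_of(big)[1, 1], 0)           # pushes sx down
  smallq <- feasible; smallq[2, 1] <- 0.02   # sx below beta
  expect_lt(grad_of(smallq)[1, 2], 0)        # pushes sx up
  off <- feasible; off[3, 3] <- 0.95         # tx beyond gamma
  expect_gt(grad_of(off)[3, 3], 0)
  expect_true(all(grad_of(feasible) == 0))
  # finite-difference agreement at random (in)feasible points
  set.seed(23)
  for (rep in 1:5) {
    q <- matrix(stats::runif(16, -0.9, 0.9), 4, 4)
    g <- grad_of(q)
    f <- function(v) constraint_losses(matrix(v, 4, byrow = FALSE),
                                       n_modules = 4)$L_STN
    th <- matrix(t(q), 16, 1)
    fv <- function(v) constraint_losses(matrix(v, 16, 1), n_modules = 4)$L_STN
    idx <- sample(16, 6)
    num <- fd_grad_at(fv, th, idx, eps = 1e-6)
    expect_equal(num, as.vector(g)[idx], tolerance = 1e-4)
  }
})

test_that("GPN-ST forward yields four region heads and a 6-head embedding", {
  m <- tiny_st(num_classes = 9)
  x <- array(stats::rnorm(96 * 48 * 3 * 2), c(96, 48, 3, 2))
  out <- ag_no_grad(forward_train_st(m, x, training = FALSE))
  expect_length(out$ST_feat, 4)
  expect_length(out$ST_logits, 4)
  ch <- m$config$channels
  for (f in out$ST_feat) expect_equal(nrow(ag_value(f)), ch$high)
  for (lg in out$ST_logits) expect_equal(dim(ag_value(lg)), c(9L, 2L))
  # 6 heads total: G, M, ST1..ST4
  expect_equal(embedding_dim(m), 6 * m$config$feat_dim)
  e <- embed_images(m, x)
  expect_equal(ncol(e), 6 * m$config$feat_dim)
  expect_identical(e, embed_images(m, x))
})

test_that("identity-forced transformers reproduce the Global pooled feature", {
  m <- tiny_st(stn_grid = c(12L, 6L))  # grid = full stage-4 map extent
  for (mm in 1:4) {
    m$params[[sprintf("stn%d.fc2.w", mm)]]$value[] <- 0
    m$params[[sprintf("stn%d.fc2.b", mm)]]$value <- c(1, 1, 0, 0)
  }
  x <- array(stats::rnorm(96 * 48 * 3 * 2), c(96, 48, 3, 2))
  out <- ag_no_grad(forward_train_st(m, x, training = FALSE))
  g <- ag_value(out$G)
  for (mm in 1:4) {
    expect_lt(max(abs(ag_value(out$ST_feat[[mm]]) - g)), 1e-4)
  }
})

test_that("region rectangles map back to pixel coordinates", {
  img <- array(0.5, c(40, 20, 3))
  full <- visualize_regions(img, matrix(c(1, 1, 0, 0), 1))
  r <- attr(full, "rects")
  expect_equal(unlist(r[1, 2:5], use.names = FALSE), c(1, 20, 1, 40))
  half <- visualize_regions(img, matrix(c(0.5, 0.5, 0, 0), 1))
  r2 <- attr(half, "rects")
  expect_equal(unlist(r2[1, 2:5], use.names = FALSE),
               c(round(1 + 0.25 * 19), round(1 + 0.75 * 19),
                 round(1 + 0.25 * 39), round(1 + 0.75 * 39)))
  m <- tiny_st()
  quads <- t(vapply(1:4, cowreid:::stn_init_quadruple, numeric(4)))
  anno <- visualize_regions(img, quads)
  rects <- attr(anno, "rects")
  expect_equal(nrow(rects), 4)
  expect_equal(nrow(unique(rects[, 2:5])), 4)  # four distinct rectangles
})
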