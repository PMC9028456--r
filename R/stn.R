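# Spatial-transformer Part branch: localization networks predicting one
# scale+shift affine quadruple per module, constrained bilinear region
# sampling, and the four soft constraint losses that keep the regions
# in-range, positive, on-canvas and mutually separated.
#
# The affine matrix is restricted to [[sx, 0, tx], [0, sy, ty]] in normalized
# [-1, 1] source coordinates: sx, sy are region/source extent ratios and
# (tx, ty) is the region center. Constraints are applied as losses only,
# never as hard clamps.

# Module-specific warm-start quadruples (sx, sy, tx, ty): regions begin at
# scale 0.3 with centers on the four diagonal positions, inside the feasible
# set of all four constraint losses.
stn_init_quadruple <- function(m) {
  cx <- c(-0.3, 0.3, -0.3, 0.3)[(m - 1L) %% 4L + 1L]
  cy <- c(-0.3, -0.3, 0.3, 0.3)[(m - 1L) %% 4L + 1L]
  c(0.3, 0.3, cx, cy)
}

add_stn_module <- function(model, m, ch) {
  pre <- paste0("stn", m)
  add_conv(model, paste0(pre, ".conv"), 1, 1, ch$high, ch$loc_c)
  add_linear(model, paste0(pre, ".fc1"), ch$loc_c, ch$loc_h)
  # final layer: zero weights + quadruple bias, so modules start exactly at
  # their warm-start regions regardless of the input
  add_linear(model, paste0(pre, ".fc2"), ch$loc_h, 4L, zero_init = TRUE)
  model$params[[paste0(pre, ".fc2.b")]]$value <- stn_init_quadruple(m)
  invisible(model)
}

#' Localize attention regions on the stage-4 feature map
#'
#' Each spatial-transformer module runs its own localization network (1x1
#' convolution, global average pooling, two linear layers) and emits one
#' unconstrained affine quadruple (sx, sy, tx, ty) per image. Range
#' constraints are applied through [constraint_losses()], not here.
#'
#' @param model a `gpn_model` with variant `"gpn_st"`
#' @param high_map stage-4 feature map `[H, W, C_high, N]` (array or node)
#' @param training logical, passed to nothing here but kept for symmetry
#' @return node/matrix of dim `[4 * n_stn, N]`; rows grouped per module
#' @export
localize <- function(model, high_map, training = TRUE) {
  cfg <- model$config
  outs <- vector("list", cfg$n_stn)
  for (m in seq_len(cfg$n_stn)) {
    pre <- paste0("stn", m)
    h <- op_gap(op_relu(apply_conv(model, paste0(pre, ".conv"), high_map)))
    h <- op_relu(apply_linear(model, paste0(pre, ".fc1"), h))
    outs[[m]] <- apply_linear(model, paste0(pre, ".fc2"), h)
  }
  op_concat_rows(outs)
}

#' Sample an affine region from a feature map
#'
#' Bilinear resampling of `high_map` under the scale+shift affine
#' `[[sx,0,tx],[0,sy,ty]]` in normalized align-corners coordinates, zero
#' padding outside the source. With `sx = sy = 1`, `tx = ty = 0` and
#' `out_hw` equal to the source size this is the identity.
#'
#' @param high_map feature map `[H, W, C, N]` (array or node)
#' @param affine_params matrix/node `[4, N]` with rows sx, sy, tx, ty (a
#'   length-4 vector is recycled over the batch)
#' @param out_hw output grid size (height, width), default `c(6, 6)`
#' @return sampled map `[out_hw[1], out_hw[2], C, N]`
#' @export
sample_region <- function(high_map, affine_params, out_hw = c(6L, 6L)) {
  if (any(out_hw < 1)) stop("sample_region: out_hw must be >= 1")
  n <- dim(ag_value(high_map))[4]
  if (!is_node(affine_params)) {
    affine_params <- if (is.matrix(affine_params)) affine_params
                     else matrix(affine_params, 4L, n)
  }
  op_grid_sample(high_map, affine_params, out_hw[1], out_hw[2])
}

#' Constraint-loss configuration
#'
#' Defaults: `alpha = 0.5` (scale range), `beta = 0.1` (scale
#' positivity floor), `gamma = 0.71` (center range; pass `gamma = sqrt(2)/2`
#' for the exact half-diagonal), `delta = 0.4` (squared center separation),
#' `lambda1 = lambda2 = 0.1` (weights of the positivity and exclusion terms).
#' @param alpha,beta,gamma,delta,lambda1,lambda2 positive reals
#' @return a `stn_constraints` list
#' @export
constraint_config <- function(alpha = 0.5, beta = 0.1, gamma = 0.71,
                              delta = 0.4, lambda1 = 0.1, lambda2 = 0.1) {
  stopifnot(alpha > 0, beta > 0, gamma > 0, delta > 0, lambda1 > 0, lambda2 > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 lambda1 = lambda1, lambda2 = lambda2),
            class = "stn_constraints")
}

# Core evaluator + gradients, vectorized over modules (rows of sx etc. are
# modules, columns are images). Values are per-image sums over modules /
# module pairs, then averaged over the batch.
stn_constraint_core <- function(sx, sy, tx, ty, cfg) {
  B <- ncol(sx); M <- nrow(sx)
  zg <- function() matrix(0, M, B)
  hinge_sq <- function(v, lim) {
    e <- pmax(abs(v) - lim, 0)
    list(val = e^2, grad = 2 * e * sign(v))
  }
  ss_x <- hinge_sq(sx, cfg$alpha); ss_y <- hinge_sq(sy, cfg$alpha)
  l_ss <- sum(ss_x$val + ss_y$val) / B
  g_ss <- list(sx = ss_x$grad / B, sy = ss_y$grad / B, tx = zg(), ty = zg())
  sp_x <- cfg$beta - sx > 0; sp_y <- cfg$beta - sy > 0
  l_sp <- (sum(pmax(cfg$beta - sx, 0)) + sum(pmax(cfg$beta - sy, 0))) / B
  g_sp <- list(sx = -(sp_x + 0) / B, sy = -(sp_y + 0) / B, tx = zg(), ty = zg())
  ts_x <- hinge_sq(tx, cfg$gamma); ts_y <- hinge_sq(ty, cfg$gamma)
  l_ts <- sum(ts_x$val + ts_y$val) / B
  g_ts <- list(sx = zg(), sy = zg(), tx = ts_x$grad / B, ty = ts_y$grad / B)
  l_te <- 0
  g_te <- list(sx = zg(), sy = zg(), tx = zg(), ty = zg())
  if (M >= 2) {
    for (i in seq_len(M - 1)) {
      for (j in (i + 1):M) {
        dx <- tx[i, ] - tx[j, ]; dy <- ty[i, ] - ty[j, ]
        d2 <- dx^2 + dy^2
        act <- d2 < cfg$delta
        l_te <- l_te + sum((cfg$delta - d2)[act]) / B
        g_te$tx[i, ] <- g_te$tx[i, ] - 2 * dx * act / B
        g_te$tx[j, ] <- g_te$tx[j, ] + 2 * dx * act / B
        g_te$ty[i, ] <- g_te$ty[i, ] - 2 * dy * act / B
        g_te$ty[j, ] <- g_te$ty[j, ] + 2 * dy * act / B
      }
    }
  }
  list(values = c(L_SS = l_ss, L_SP = l_sp, L_TS = l_ts, L_TE = l_te),
       grads = list(L_SS = g_ss, L_SP = g_sp, L_TS = g_ts, L_TE = g_te))
}

theta_to_blocks <- function(tv, n_mod) {
  # tv: [4*n_mod, B]; returns module x image matrices per parameter
  arr <- array(tv, dim = c(4L, n_mod, ncol(tv)))
  list(sx = matrix(arr[1, , ], n_mod), sy = matrix(arr[2, , ], n_mod),
       tx = matrix(arr[3, , ], n_mod), ty = matrix(arr[4, , ], n_mod))
}

blocks_to_theta <- function(gb, n_mod, B) {
  arr <- array(0, dim = c(4L, n_mod, B))
  arr[1, , ] <- gb$sx; arr[2, , ] <- gb$sy; arr[3, , ] <- gb$tx; arr[4, , ] <- gb$ty
  matrix(arr, 4L * n_mod, B)
}

#' Soft constraint losses on the affine parameters
#'
#' For per-image module quadruples, computes
#' `L_SS = sum_m max(|sx|-alpha,0)^2 + max(|sy|-alpha,0)^2` (scale range),
#' `L_SP = sum_m max(0,beta-sx) + max(0,beta-sy)` (positivity),
#' `L_TS = sum_m max(|tx|-gamma,0)^2 + max(|ty|-gamma,0)^2` (center range),
#' `L_TE = sum_{i<j} max(0, delta - ((tx_i-tx_j)^2 + (ty_i-ty_j)^2))`
#' (mutual exclusion of region centers), and the combination
#' `L_STN = L_SS + lambda1 L_SP + L_TS + lambda2 L_TE`. All terms are
#' averaged over the batch. Each loss is zero exactly on its feasible set.
#'
#' @param params affine parameters: a `[n_modules, 4]` matrix (single image,
#'   columns sx, sy, tx, ty), a `[4 * n_modules, N]` matrix/node as produced
#'   by [localize()], or a `[n_modules, 4, N]` array
#' @param config a [constraint_config()]
#' @param n_modules number of modules; required only for the `[4*M, N]` form
#' @return named list `L_SS`, `L_SP`, `L_TS`, `L_TE`, `L_STN` of scalars
#'   (nodes if `params` is a node and recording is active)
#' @export
constraint_losses <- function(params, config = constraint_config(),
                              n_modules = NULL) {
  tv <- ag_value(params)
  if (is_node(params) || (is.matrix(tv) && !is.null(n_modules))) {
    n_mod <- if (is.null(n_modules)) nrow(tv) %/% 4L else as.integer(n_modules)
    blocks <- theta_to_blocks(tv, n_mod)
  } else if (is.matrix(tv) && ncol(tv) == 4L) {
    n_mod <- nrow(tv)
    blocks <- list(sx = matrix(tv[, 1]), sy = matrix(tv[, 2]),
                   tx = matrix(tv[, 3]), ty = matrix(tv[, 4]))
  } else if (length(dim(tv)) == 3L) {
    n_mod <- dim(tv)[1]
    blocks <- list(sx = matrix(tv[, 1, ], n_mod), sy = matrix(tv[, 2, ], n_mod),
                   tx = matrix(tv[, 3, ], n_mod), ty = matrix(tv[, 4, ], n_mod))
  } else stop("constraint_losses: unrecognized parameter layout")
  if (n_mod < 2) {
    warning("fewer than two modules: mutual-exclusion term L_TE is 0")
  }
  core <- stn_constraint_core(blocks$sx, blocks$sy, blocks$tx, blocks$ty, config)
  B <- ncol(blocks$sx)
  mk <- function(nm) {
    ag_node(core$values[[nm]], backward = function(node) {
      if (!is_node(params)) return(invisible(NULL))
      g <- blocks_to_theta(core$grads[[nm]], n_mod, B) * node$grad
      ag_accum(params, g)
    })
  }
  terms <- lapply(c("L_SS", "L_SP", "L_TS", "L_TE"), mk)
  names(terms) <- c("L_SS", "L_SP", "L_TS", "L_TE")
  w <- c(1, config$lambda1, 1, config$lambda2)
  l_stn <- op_scalar_lincomb(terms, w)
  out <- c(terms, list(L_STN = l_stn))
  if (!is_node(params)) out <- lapply(out, ag_value)
  out
}

#' Map normalized affine regions to pixel rectangles and annotate an image
#'
#' Each module's region spans `[t - s, t + s]` in normalized coordinates;
#' rectangles are mapped back to input pixel coordinates (align-corners) and
#' drawn as colored borders, labeled in module order.
#'
#' @param image `[H, W, 3]` array in `[0, 1]`
#' @param affine_params `[n_modules, 4]` matrix with columns sx, sy, tx, ty
#' @return the annotated image, with attribute `"rects"`: a data.frame of
#'   module, x0, x1, y0, y1 pixel coordinates
#' @export
visualize_regions <- function(image, affine_params) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  H <- dim(image)[1]; W <- dim(image)[2]
  px <- function(x, n) 1 + (x + 1) * (n - 1) / 2
  cols <- matrix(c(1, 0, 0,  0, 0.8, 0,  0.2, 0.4, 1,  1, 0.8, 0), 3)
  rects <- data.frame(module = integer(), x0 = numeric(), x1 = numeric(),
                      y0 = numeric(), y1 = numeric())
  out <- image
  for (m in seq_len(nrow(affine_params))) {
    sx <- affine_params[m, 1]; sy <- affine_params[m, 2]
    tx <- affine_params[m, 3]; ty <- affine_params[m, 4]
    x0 <- max(1, round(px(tx - sx, W))); x1 <- min(W, round(px(tx + sx, W)))
    y0 <- max(1, round(px(ty - sy, H))); y1 <- min(H, round(px(ty + sy, H)))
    rects[m, ] <- list(m, x0, x1, y0, y1)
    cc <- cols[, (m - 1L) %% 4L + 1L]
    for (ch in 1:3) {
      out[y0:y1, c(x0, x1), ch] <- cc[ch]
      out[c(y0, y1), x0:x1, ch] <- cc[ch]
    }
  }
  attr(out, "rects") <- rects
  out
}
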