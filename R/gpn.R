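# Forward passes of the GPN and GPN-ST models and test-time embedding
# assembly.
#
# Branch layout (GPN):
#   Global branch: stage-4 map -> GAP and GMP -> G_Avg, G_Max (C_high each)
#     -> G = G_Avg + G_Max -> head -> G_Down (feat_dim), G_logits.
#   Middle branch: stage-3 map -> same dual pooling -> M (C_mid) -> head.
#   Part branch:  stage-4 map partitioned into `stripes` uniform bands; per
#     band average and max pooling; band vectors concatenated into P_Avg and
#     P_Max (stripes x C_high), summed into P; each band slice of P feeds its
#     own head.
# GPN-ST replaces the Part branch by `n_stn` spatial-transformer modules
# (see stn.R); triplet losses are not attached to its Part branch.

global_middle_forward <- function(model, maps, training) {
  g_avg <- op_gap(maps$high); g_max <- op_gmp(maps$high)
  g <- op_add(g_avg, g_max)
  hg <- head_forward(model, "G", g, training)
  m_avg <- op_gap(maps$mid); m_max <- op_gmp(maps$mid)
  m <- op_add(m_avg, m_max)
  hm <- head_forward(model, "M", m, training)
  list(G_Avg = g_avg, G_Max = g_max, G = g, G_Down = hg$feat, G_logits = hg$logits,
       M_Avg = m_avg, M_Max = m_max, M = m, M_Down = hm$feat, M_logits = hm$logits)
}

stripe_bounds <- function(extent, stripes) {
  if (extent < stripes) {
    stop(sprintf(paste0("stripe partition needs a stage-4 map extent of at ",
                        "least %d along the partition axis, got %d; ",
                        "increase the input size"), stripes, extent))
  }
  cut <- round(seq(0, extent, length.out = stripes + 1))
  cbind(lo = cut[-length(cut)] + 1, hi = cut[-1])
}

#' GPN training forward pass
#'
#' Runs one batch through backbone and all three branches, returning every
#' intermediate the training objective needs.
#'
#' @param model a `gpn_model` built with variant `"gpn"`
#' @param images numeric array `[H, W, 3, N]`, already normalized
#' @param training logical; `TRUE` uses batch statistics in batch norm
#' @return named list with `G_Avg`, `G_Max`, `G`, `G_Down`, `G_logits`, the
#'   `M_*` equivalents, `P_Avg`, `P_Max`, `P` (flattened stripes x C_high),
#'   `P_stripe` (list), `P_Down` (list), `P_logits` (list)
#' @export
forward_train <- function(model, images, training = TRUE) {
  stopifnot(model$config$variant == "gpn")
  maps <- backbone_forward(model, images, training)
  out <- global_middle_forward(model, maps, training)
  cfg <- model$config
  d <- dim(ag_value(maps$high))
  horiz <- cfg$stripe_orientation == "horizontal"
  bounds <- stripe_bounds(if (horiz) d[1] else d[2], cfg$stripes)
  avg_parts <- vector("list", cfg$stripes)
  max_parts <- vector("list", cfg$stripes)
  for (k in seq_len(cfg$stripes)) {
    band <- if (horiz) op_slice_h(maps$high, bounds[k, 1], bounds[k, 2])
            else op_slice_w(maps$high, bounds[k, 1], bounds[k, 2])
    avg_parts[[k]] <- op_gap(band)
    max_parts[[k]] <- op_gmp(band)
  }
  p_avg <- op_concat_rows(avg_parts)
  p_max <- op_concat_rows(max_parts)
  p <- op_add(p_avg, p_max)
  ch <- d[3]
  p_stripe <- vector("list", cfg$stripes)
  p_down <- vector("list", cfg$stripes)
  p_logits <- vector("list", cfg$stripes)
  for (k in seq_len(cfg$stripes)) {
    p_stripe[[k]] <- op_rows(p, (k - 1L) * ch + 1L, k * ch)
    hk <- head_forward(model, paste0("P", k), p_stripe[[k]], training)
    p_down[[k]] <- hk$feat
    p_logits[[k]] <- hk$logits
  }
  c(out, list(P_Avg = p_avg, P_Max = p_max, P = p,
              P_stripe = p_stripe, P_Down = p_down, P_logits = p_logits))
}

#' GPN-ST training forward pass
#'
#' Global and Middle branches are identical to [forward_train()]; the Part
#' branch localizes `n_stn` affine regions on the stage-4 map, samples each by
#' bilinear interpolation, dual-pools and feeds one head per region.
#'
#' @inheritParams forward_train
#' @return named list with the `G_*` and `M_*` fields of [forward_train()]
#'   plus `theta` (the `[4 * n_stn, N]` affine parameter node; rows grouped
#'   per module as sx, sy, tx, ty), `ST_region` (list of sampled maps),
#'   `ST_feat` (list of pooled C_high vectors), `ST_Down`, `ST_logits`
#' @export
forward_train_st <- function(model, images, training = TRUE) {
  stopifnot(model$config$variant == "gpn_st")
  maps <- backbone_forward(model, images, training)
  out <- global_middle_forward(model, maps, training)
  cfg <- model$config
  theta <- localize(model, maps$high, training)
  st_region <- vector("list", cfg$n_stn)
  st_feat <- vector("list", cfg$n_stn)
  st_down <- vector("list", cfg$n_stn)
  st_logits <- vector("list", cfg$n_stn)
  for (m in seq_len(cfg$n_stn)) {
    th_m <- op_rows(theta, (m - 1L) * 4L + 1L, m * 4L)
    st_region[[m]] <- op_grid_sample(maps$high, th_m,
                                     cfg$stn_grid[1], cfg$stn_grid[2])
    st_feat[[m]] <- op_add(op_gap(st_region[[m]]), op_gmp(st_region[[m]]))
    hm <- head_forward(model, paste0("ST", m), st_feat[[m]], training)
    st_down[[m]] <- hm$feat
    st_logits[[m]] <- hm$logits
  }
  c(out, list(theta = theta, ST_region = st_region, ST_feat = st_feat,
              ST_Down = st_down, ST_logits = st_logits))
}

#' Test-time embeddings
#'
#' Extracts the concatenated post-BN head features in evaluation mode (batch
#' norm uses running statistics; nothing is recorded for backpropagation).
#' Concatenation order is fixed: `[G_Down, M_Down, P_Down 1..6]` for GPN
#' (8 x feat_dim) and `[G_Down, M_Down, ST_Down 1..4]` for GPN-ST
#' (6 x feat_dim).
#'
#' @param model a `gpn_model`
#' @param images array `[H, W, 3, N]` of normalized images
#' @param batch_size mini-batch size used for extraction
#' @return numeric matrix `[N, embedding_dim(model)]`, one row per image
#' @export
embed_images <- function(model, images, batch_size = 8L) {
  stopifnot(length(dim(images)) == 4L)
  n <- dim(images)[4]
  fwd <- if (model$config$variant == "gpn") forward_train else forward_train_st
  rows <- vector("list", ceiling(n / batch_size))
  bi <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out <- ag_no_grad(fwd(model, images[, , , idx, drop = FALSE], training = FALSE))
    parts <- if (model$config$variant == "gpn") {
      c(list(out$G_Down, out$M_Down), out$P_Down)
    } else {
      c(list(out$G_Down, out$M_Down), out$ST_Down)
    }
    emb <- do.call(rbind, lapply(parts, ag_value))
    bi <- bi + 1L
    rows[[bi]] <- t(emb)
  }
  do.call(rbind, rows)
}

#' Segment boundaries of the test-time embedding
#'
#' Documents and fixes the concatenation order of [embed_images()]: each row
#' names the head whose feature occupies columns `from:to`.
#' @param model a `gpn_model`
#' @return data.frame with columns `head`, `from`, `to`
#' @export
embedding_layout <- function(model) {
  cfg <- model$config
  heads <- if (cfg$variant == "gpn") {
    c("G", "M", paste0("P", seq_len(cfg$stripes)))
  } else {
    c("G", "M", paste0("ST", seq_len(cfg$n_stn)))
  }
  to <- seq_along(heads) * cfg$feat_dim
  data.frame(head = heads, from = to - cfg$feat_dim + 1L, to = to)
}
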