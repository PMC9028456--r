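# Open-set ranking evaluation: cosine similarity, CMC Rank-k, AP/mAP, the
# capped-gallery sweep, and the raw-pixel nearest-centroid baseline.

#' Cosine similarity between two embedding matrices
#'
#' @param a,b numeric matrices `[n, D]`, one embedding per row, equal `D`
#' @return `[nrow(a), nrow(b)]` matrix of cosine similarities in `[-1, 1]`
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), ncol(a) == ncol(b))
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  if (any(na == 0)) stop("zero-norm embedding in rows of a: ",
                         paste(which(na == 0), collapse = ", "))
  if (any(nb == 0)) stop("zero-norm embedding in rows of b: ",
                         paste(which(nb == 0), collapse = ", "))
  (a / na) %*% t(b / nb)
}

#' Average precision of one ranked retrieval list
#'
#' `AP = (1/N) * sum_i i / p_i`, where `N` is the number of gallery items
#' sharing the query identity and `p_i` the 1-based rank of the i-th correct
#' match. A list with its relevant items at ranks 1 and 3 (`N = 2`) scores
#' `(1/1 + 2/3) / 2 = 5/6`.
#'
#' @param ranked_gallery_ids gallery identities in descending-similarity order
#' @param query_id the query identity
#' @return AP in `(0, 1]`
#' @export
average_precision <- function(ranked_gallery_ids, query_id) {
  pos <- which(ranked_gallery_ids == query_id)
  if (!length(pos)) {
    stop("no gallery image shares the query identity (query invariant ",
         "violated upstream)")
  }
  mean(seq_along(pos) / pos)
}

#' CMC Rank-k accuracy
#'
#' Fraction of queries whose top-k ranked gallery items contain at least one
#' correct identity. Ties in similarity are broken by stable gallery index
#' order.
#'
#' @param similarities `[n_query, n_gallery]` similarity matrix
#' @param query_ids,gallery_ids identity vectors
#' @param k rank depth (`1 <= k <= n_gallery`)
#' @return Rank-k accuracy in `[0, 1]`
#' @export
rank_k <- function(similarities, query_ids, gallery_ids, k) {
  stopifnot(k >= 1)
  if (k > length(gallery_ids)) {
    stop("k = ", k, " exceeds gallery size ", length(gallery_ids))
  }
  hits <- vapply(seq_along(query_ids), function(i) {
    ord <- order(-similarities[i, ])  # stable: ties keep gallery order
    any(gallery_ids[ord[seq_len(k)]] == query_ids[i])
  }, TRUE)
  mean(hits)
}

#' Mean average precision over all queries
#' @inheritParams rank_k
#' @return mAP in `(0, 1]`
#' @export
mean_ap <- function(similarities, query_ids, gallery_ids) {
  mean(vapply(seq_along(query_ids), function(i) {
    ord <- order(-similarities[i, ])
    average_precision(gallery_ids[ord], query_ids[i])
  }, 0))
}

normalize_images <- function(x, mean = 0.5, sd = 0.5) (x - mean) / sd

load_image_stack <- function(paths, size = NULL) {
  imgs <- lapply(paths, load_image)
  if (!is.null(size)) {
    imgs <- lapply(imgs, function(im) {
      if (all(dim(im)[1:2] == size)) im else resize_image(im, size)
    })
  }
  d <- dim(imgs[[1]])
  array(unlist(imgs, use.names = FALSE), dim = c(d, length(imgs)))
}

embed_dataset_split <- function(model, dataset, rows, batch_size = 8L) {
  size <- model$config$input_size
  stack <- load_image_stack(dataset$records$path[rows], size)
  embed_images(model, normalize_images(stack), batch_size)
}

#' Evaluate a model over capped gallery subsets
#'
#' Embeds all query and gallery images once (evaluation mode, test batch
#' size 8 by default), then scores Rank-1/5/10 and mAP against each capped
#' gallery view (`Gallery n` keeps at most `n` seeded-random images per
#' identity). Rank-k values with `k` larger than the capped gallery are NA.
#'
#' @param model a trained `gpn_model`
#' @param dataset a `reid_dataset` with query and gallery splits
#' @param gallery_caps per-identity caps to sweep
#' @param seed gallery-view selection seed (recorded in the report)
#' @param batch_size embedding batch size
#' @return an `eval_report` data.frame: one row per cap with columns
#'   `cap`, `rank1`, `rank5`, `rank10`, `map`
#' @export
evaluate_model <- function(model, dataset,
                           gallery_caps = c(1, 2, 3, 4, 5, 10, 15, 20),
                           seed = 1L, batch_size = 8L) {
  recs <- dataset$records
  q_rows <- which(recs$split == "query")
  g_rows <- which(recs$split == "gallery")
  stopifnot(length(q_rows) > 0, length(g_rows) > 0)
  q_emb <- embed_dataset_split(model, dataset, q_rows, batch_size)
  g_emb <- embed_dataset_split(model, dataset, g_rows, batch_size)
  q_ids <- recs$identity[q_rows]
  report <- lapply(gallery_caps, function(cap) {
    view <- make_gallery_view(dataset, cap, seed)
    sel <- match(rownames(view), rownames(recs[g_rows, , drop = FALSE]))
    sub <- g_emb[sel, , drop = FALSE]
    sim <- cosine_similarity(q_emb, sub)
    g_ids <- view$identity
    rk <- function(k) if (k <= nrow(view)) rank_k(sim, q_ids, g_ids, k) else NA_real_
    data.frame(cap = cap, rank1 = rk(1), rank5 = rk(5), rank10 = rk(10),
               map = mean_ap(sim, q_ids, g_ids))
  })
  out <- do.call(rbind, report)
  attr(out, "gallery_seed") <- seed
  attr(out, "model_tag") <- model$config$variant
  class(out) <- c("eval_report", "data.frame")
  out
}

#' Raw-pixel nearest-centroid baseline
#'
#' Downsamples every test image to a small grayscale raster, averages the
#' gallery rasters per identity, and assigns each query to the nearest
#' centroid (Euclidean). Establishes the floor any learned embedding must
#' beat and confirms the synthetic fixture carries identity signal.
#'
#' @param dataset a `reid_dataset`
#' @param size downsampled (height, width), default 16x8
#' @return list with `rank1` and the per-query correctness vector
#' @export
nearest_centroid_baseline <- function(dataset, size = c(16L, 8L)) {
  recs <- dataset$records
  gray_feats <- function(rows) {
    t(vapply(recs$path[rows], function(p) {
      im <- resize_image(load_image(p), size)
      as.vector((im[, , 1] + im[, , 2] + im[, , 3]) / 3)
    }, numeric(prod(size))))
  }
  q_rows <- which(recs$split == "query")
  g_rows <- which(recs$split == "gallery")
  qf <- gray_feats(q_rows); gf <- gray_feats(g_rows)
  g_ids <- recs$identity[g_rows]
  ids <- sort(unique(g_ids))
  cent <- t(vapply(ids, function(id) colMeans(gf[g_ids == id, , drop = FALSE]),
                   numeric(ncol(gf))))
  d2 <- outer(rowSums(qf^2), rowSums(cent^2), "+") - 2 * qf %*% t(cent)
  pred <- ids[max.col(-d2, ties.method = "first")]
  correct <- pred == recs$identity[q_rows]
  list(rank1 = mean(correct), correct = correct)
}
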