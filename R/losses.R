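# Training objectives: hinge triplet loss with batch-hard mining,
# label-smoothed softmax cross-entropy, and the joint GPN / GPN-ST losses.

#' Triplet loss configuration
#' @param margin hinge margin on squared Euclidean distances (default 0.3)
#' @param mining `"batch_hard"` (hardest positive / hardest negative per
#'   anchor) or `"all_valid"` (mean over every valid triplet)
#' @return a `triplet_config` list
#' @export
triplet_config <- function(margin = 0.3, mining = c("batch_hard", "all_valid")) {
  stopifnot(margin > 0)
  structure(list(margin = margin, mining = match.arg(mining)),
            class = "triplet_config")
}

pairwise_sqdist <- function(f) {
  # f: [D, N]; returns N x N squared Euclidean distances
  g <- crossprod(f)
  nn <- diag(g)
  d2 <- outer(nn, nn, "+") - 2 * g
  pmax(d2, 0)
}

#' Triplet loss over a feature batch
#'
#' For each anchor `a`, the hinge `max(0, D(a,p)^2 - D(a,n)^2 + margin)` on
#' squared Euclidean distances; `batch_hard` mining selects the farthest
#' positive and nearest negative per anchor, `all_valid` averages over every
#' (anchor, positive, negative) triplet. The result is the mean over anchors
#' (or triplets). Batches from [pk_batches()] guarantee the required
#' positives and negatives.
#'
#' @param features `[D, N]` feature matrix (or node), one column per image
#' @param labels integer identity labels, length N
#' @param config a [triplet_config()]
#' @return scalar loss (node if `features` is a node and recording is active)
#' @export
triplet_loss <- function(features, labels, config = triplet_config()) {
  fv <- ag_value(features)
  n <- ncol(fv)
  stopifnot(length(labels) == n)
  same <- outer(labels, labels, "==")
  pos_mask <- same; diag(pos_mask) <- FALSE
  neg_mask <- !same
  if (any(rowSums(pos_mask) == 0) || any(rowSums(neg_mask) == 0)) {
    stop("triplet_loss: every anchor needs at least one positive and one ",
         "negative in the batch; use an identity-balanced PK sampler")
  }
  d2 <- pairwise_sqdist(fv)
  A <- matrix(0, n, n)  # d loss / d d2[anchor, other]
  if (config$mining == "batch_hard") {
    loss <- 0
    for (i in seq_len(n)) {
      pj <- which(pos_mask[i, ]); nj <- which(neg_mask[i, ])
      p <- pj[which.max(d2[i, pj])]
      ng <- nj[which.min(d2[i, nj])]
      term <- d2[i, p] - d2[i, ng] + config$margin
      if (term > 0) {
        loss <- loss + term
        A[i, p] <- A[i, p] + 1 / n
        A[i, ng] <- A[i, ng] - 1 / n
      }
    }
    loss <- loss / n
  } else {
    loss <- 0; total <- 0
    contrib <- list()
    for (i in seq_len(n)) {
      pj <- which(pos_mask[i, ]); nj <- which(neg_mask[i, ])
      total <- total + length(pj) * length(nj)
    }
    for (i in seq_len(n)) {
      pj <- which(pos_mask[i, ]); nj <- which(neg_mask[i, ])
      terms <- outer(d2[i, pj], d2[i, nj], function(a, b) a - b + config$margin)
      act <- terms > 0
      loss <- loss + sum(terms[act])
      if (any(act)) {
        A[i, pj] <- A[i, pj] + rowSums(act) / total
        A[i, nj] <- A[i, nj] - colSums(act) / total
      }
    }
    loss <- loss / total
  }
  out <- ag_node(loss, backward = function(node) {
    S <- A + t(A)
    gf <- 2 * (fv %*% (diag(rowSums(S)) - S)) * node$grad
    ag_accum(features, gf)
  })
  if (is_node(features)) out else ag_value(out)
}

#' Label-smoothing configuration
#' @param epsilon smoothing mass in `[0, 1)` (default 0.1)
#' @return a `smoothing_config` list
#' @export
smoothing_config <- function(epsilon = 0.1) {
  stopifnot(epsilon >= 0, epsilon < 1)
  structure(list(epsilon = epsilon), class = "smoothing_config")
}

#' Label-smoothed softmax cross-entropy
#'
#' The one-hot target is replaced by `q_y = 1 - (N-1) epsilon / N` on the true
#' class and `q_other = epsilon / N` elsewhere (`sum(q) = 1`); the loss is the
#' cross-entropy between `q` and the log-softmax of the logits, averaged over
#' the batch. `epsilon = 0` recovers standard cross-entropy.
#'
#' @param logits `[N_classes, B]` matrix (or node)
#' @param labels 0-based integer class labels, length B
#' @param config a [smoothing_config()]
#' @return scalar loss (node if `logits` is a node and recording is active)
#' @export
label_smooth_ce <- function(logits, labels, config = smoothing_config()) {
  lv <- ag_value(logits)
  ncls <- nrow(lv); B <- ncol(lv)
  stopifnot(ncls >= 2, length(labels) == B)
  if (any(labels < 0 | labels >= ncls)) {
    stop("label_smooth_ce: labels must lie in [0, ", ncls, ")")
  }
  eps <- config$epsilon
  mx <- apply(lv, 2, max)
  sh <- sweep(lv, 2, mx)
  lse <- log(colSums(exp(sh))) + mx
  logp <- sweep(lv, 2, lse)
  q <- matrix(eps / ncls, ncls, B)
  q[cbind(labels + 1L, seq_len(B))] <- 1 - (ncls - 1) * eps / ncls
  loss <- -sum(q * logp) / B
  out <- ag_node(loss, backward = function(node) {
    p <- exp(logp)
    ag_accum(logits, (p - q) / B * node$grad)
  })
  if (is_node(logits)) out else ag_value(out)
}

#' Joint GPN loss
#'
#' `L_T` sums the six triplet losses (on `G_Avg`, `G_Max`, `M_Avg`, `M_Max`,
#' `P_Avg`, `P_Max`); `L_ID` sums the eight classification losses (Global,
#' Middle, six stripes). The total is `L_T / 6 + L_ID / 8`.
#'
#' @param outputs list from [forward_train()]
#' @param labels 0-based integer class labels, length batch
#' @param triplet a [triplet_config()]
#' @param smoothing a [smoothing_config()]
#' @return list with `total` (scalar or node) and `components` (named numeric
#'   vector of the 6 triplet and 8 classification terms)
#' @export
gpn_total_loss <- function(outputs, labels, triplet = triplet_config(),
                           smoothing = smoothing_config()) {
  need <- c("G_Avg", "G_Max", "M_Avg", "M_Max", "P_Avg", "P_Max",
            "G_logits", "M_logits", "P_logits")
  miss <- setdiff(need, names(outputs))
  if (length(miss)) stop("gpn_total_loss: missing branch outputs: ",
                         paste(miss, collapse = ", "))
  tri_feats <- outputs[c("G_Avg", "G_Max", "M_Avg", "M_Max", "P_Avg", "P_Max")]
  tri <- lapply(tri_feats, triplet_loss, labels = labels, config = triplet)
  names(tri) <- paste0("triplet_", names(tri_feats))
  ce <- c(list(ce_G = label_smooth_ce(outputs$G_logits, labels, smoothing),
               ce_M = label_smooth_ce(outputs$M_logits, labels, smoothing)),
          stats::setNames(lapply(outputs$P_logits, label_smooth_ce,
                                 labels = labels, config = smoothing),
                          paste0("ce_P", seq_along(outputs$P_logits))))
  terms <- c(tri, ce)
  total <- op_scalar_lincomb(terms, c(rep(1 / 6, length(tri)),
                                      rep(1 / 8, length(ce))))
  comps <- vapply(terms, function(t) as.numeric(ag_value(t)), 0)
  if (!is_node(outputs$G_Avg)) total <- ag_value(total)
  list(total = total, components = comps)
}

#' Joint GPN-ST loss
#'
#' `L_TL` sums the four triplet losses (Global and Middle branches only:
#' triplet loss is not used in the attention Part branch); `L_CL` sums the six
#' classification losses (Global, Middle, four attention regions); `L_STN` is
#' the affine-constraint loss of [constraint_losses()]. The total is
#' `L_TL / 4 + L_CL / 6 + L_STN`.
#'
#' @param outputs list from [forward_train_st()] (must carry `theta`)
#' @param labels 0-based integer class labels
#' @param triplet a [triplet_config()]
#' @param smoothing a [smoothing_config()]
#' @param constraints a [constraint_config()]
#' @return list with `total` and `components` (4 triplet + 6 classification +
#'   `L_SS`, `L_SP`, `L_TS`, `L_TE`, `L_STN`)
#' @export
gpnst_total_loss <- function(outputs, labels, triplet = triplet_config(),
                             smoothing = smoothing_config(),
                             constraints = constraint_config()) {
  need <- c("G_Avg", "G_Max", "M_Avg", "M_Max", "G_logits", "M_logits",
            "ST_logits", "theta")
  miss <- setdiff(need, names(outputs))
  if (length(miss)) stop("gpnst_total_loss: missing branch outputs: ",
                         paste(miss, collapse = ", "))
  tri_feats <- outputs[c("G_Avg", "G_Max", "M_Avg", "M_Max")]
  tri <- lapply(tri_feats, triplet_loss, labels = labels, config = triplet)
  names(tri) <- paste0("triplet_", names(tri_feats))
  ce <- c(list(ce_G = label_smooth_ce(outputs$G_logits, labels, smoothing),
               ce_M = label_smooth_ce(outputs$M_logits, labels, smoothing)),
          stats::setNames(lapply(outputs$ST_logits, label_smooth_ce,
                                 labels = labels, config = smoothing),
                          paste0("ce_ST", seq_along(outputs$ST_logits))))
  con <- constraint_losses(outputs$theta, constraints)
  terms <- c(tri, ce, list(L_STN = con$L_STN))
  total <- op_scalar_lincomb(terms, c(rep(1 / 4, length(tri)),
                                      rep(1 / 6, length(ce)), 1))
  comps <- vapply(c(tri, ce, con), function(t) as.numeric(ag_value(t)), 0)
  if (!is_node(outputs$G_Avg)) total <- ag_value(total)
  list(total = total, components = comps)
}
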