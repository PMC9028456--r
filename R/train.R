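# Optimization loop: PK batches + augmentation + joint loss + SGD with the
# step learning-rate schedule, deterministic given one seed.

#' Learning rate at a (0-based) epoch under the step schedule
#'
#' `lr0 * 10^(-#{d in decay_epochs : epoch >= d})`: with the reference
#' schedule (`lr0 = 0.02`, decays at 90 and 120) this gives 0.02 / 0.002 /
#' 0.0002 at epochs 0 / 90 / 120.
#'
#' @param epoch 0-based epoch index (vectorized)
#' @param lr0 initial learning rate
#' @param decay_epochs epochs at which the rate is divided by 10
#' @return learning rate(s)
#' @export
lr_at_epoch <- function(epoch, lr0 = 0.02, decay_epochs = c(90, 120)) {
  vapply(epoch, function(e) lr0 * 10^(-sum(e >= decay_epochs)), 0)
}

#' Training configuration
#'
#' `preset = "reference"` is the full-scale schedule: SGD momentum 0.9, weight
#' decay 5e-4, lr 0.02 divided by 10 at epochs 90 and 120, 140 epochs,
#' resnet50 backbone at 384x192, P=8 identities x K=4 images. `preset =
#' "desk"` is a CPU-scale configuration (tiny backbone at 96x48, few epochs,
#' no decay within range) whose logs are tagged non-reference.
#'
#' @param preset `"desk"` or `"reference"`
#' @param variant `"gpn"` or `"gpn_st"`
#' @param epochs,lr0,decay_epochs,momentum,weight_decay optimizer schedule
#' @param p,k PK sampler shape
#' @param margin triplet margin; `label_smooth` smoothing epsilon
#' @param seed master seed for init, sampling and augmentation
#' @param backbone,image_size,feat_dim forwarded to [model_config()]
#' @param hflip_prob,erase_prob augmentation probabilities
#' @return a `train_config` list
#' @export
train_config <- function(preset = c("desk", "reference"),
                         variant = c("gpn", "gpn_st"),
                         epochs = NULL, lr0 = 0.02,
                         decay_epochs = c(90, 120),
                         momentum = 0.9, weight_decay = 5e-4,
                         p = 8L, k = 4L, margin = 0.3, label_smooth = 0.1,
                         seed = 1L, backbone = NULL, image_size = NULL,
                         feat_dim = NULL, hflip_prob = 0.5, erase_prob = 0.5) {
  preset <- match.arg(preset)
  variant <- match.arg(variant)
  if (is.null(backbone)) backbone <- if (preset == "reference") "resnet50" else "tiny"
  if (is.null(epochs)) epochs <- if (preset == "reference") 140L else 8L
  if (is.null(image_size))
    image_size <- if (backbone == "resnet50") c(384L, 192L) else c(96L, 48L)
  structure(list(preset = preset, variant = variant, epochs = as.integer(epochs),
                 lr0 = lr0, decay_epochs = decay_epochs, momentum = momentum,
                 weight_decay = weight_decay, p = as.integer(p),
                 k = as.integer(k), margin = margin, label_smooth = label_smooth,
                 seed = as.integer(seed), backbone = backbone,
                 image_size = as.integer(image_size), feat_dim = feat_dim,
                 hflip_prob = hflip_prob, erase_prob = erase_prob),
            class = "train_config")
}

#' Train a GPN or GPN-ST model
#'
#' Runs the full loop: identity-balanced PK batches, augmentation (resize,
#' horizontal flip, random erasing), forward pass, joint loss, SGD step with
#' the step learning-rate schedule. Fully reproducible given `config$seed`
#' on one device. A NaN loss aborts with the component values of the failing
#' step.
#'
#' @param dataset a `reid_dataset` with a training split
#' @param config a [train_config()]
#' @param log_path optional JSONL file receiving one record per iteration
#' @param checkpoint_path optional path prefix; a checkpoint is written after
#'   the final epoch via [save_checkpoint()]
#' @param verbose print per-epoch summaries
#' @return list with `model`, `history` (data.frame epoch/lr/loss) and
#'   `config`
#' @export
train_model <- function(dataset, config = train_config(), log_path = NULL,
                        checkpoint_path = NULL, verbose = FALSE) {
  set.seed(config$seed)
  mcfg <- model_config(backbone = config$backbone, variant = config$variant,
                       num_classes = dataset$num_train_classes,
                       feat_dim = config$feat_dim,
                       input_size = config$image_size)
  model <- build_model(mcfg)
  fwd <- if (config$variant == "gpn") forward_train else forward_train_st
  lossfun <- function(outputs, labels) {
    tri <- triplet_config(margin = config$margin)
    smo <- smoothing_config(config$label_smooth)
    if (config$variant == "gpn") gpn_total_loss(outputs, labels, tri, smo)
    else gpnst_total_loss(outputs, labels, tri, smo)
  }
  aug <- augment_config(resize = config$image_size,
                        hflip_prob = config$hflip_prob,
                        erase_prob = config$erase_prob)
  tr_rows <- which(dataset$records$split == "train")
  cache <- lapply(dataset$records$path[tr_rows], load_image)
  names(cache) <- as.character(tr_rows)
  scfg <- sampler_config(config$p, config$k)
  params <- model_params(model)
  logcon <- if (!is.null(log_path)) file(log_path, open = "wt") else NULL
  if (!is.null(logcon)) on.exit(close(logcon), add = TRUE)
  history <- data.frame(epoch = integer(), lr = numeric(), loss = numeric())
  it <- 0L
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- lr_at_epoch(epoch, config$lr0, config$decay_epochs)
    batches <- pk_batches(dataset, scfg, seed = mix_seed(config$seed, epoch, 17))
    set.seed(mix_seed(config$seed, epoch, 23))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      imgs <- lapply(idx, function(r) augment_image(cache[[as.character(r)]], aug))
      x <- normalize_images(array(unlist(imgs, use.names = FALSE),
                                  dim = c(config$image_size, 3L, length(idx))))
      labels <- dataset$records$class_index[idx]
      lossobj <- NULL
      ag_record({
        outputs <- fwd(model, x, training = TRUE)
        lossobj <- lossfun(outputs, labels)
      })
      lv <- as.numeric(ag_value(lossobj$total))
      if (!is.finite(lv)) {
        ag_reset_tape()
        stop("non-finite loss at epoch ", epoch, " iteration ", bi, ":\n",
             paste(sprintf("  %s = %.6g", names(lossobj$components),
                           lossobj$components), collapse = "\n"))
      }
      ag_backward(lossobj$total)
      sgd_step(params, lr, config$momentum, config$weight_decay)
      ag_zero_grad(params)
      ep_loss <- ep_loss + lv
      it <- it + 1L
      if (!is.null(logcon)) {
        writeLines(jsonlite::toJSON(c(list(iter = it, epoch = epoch, lr = lr,
                                           total = lv),
                                      as.list(lossobj$components)),
                                    auto_unbox = TRUE, digits = NA), logcon)
      }
    }
    ep_loss <- ep_loss / length(batches)
    history <- rbind(history, data.frame(epoch = epoch, lr = lr, loss = ep_loss))
    if (verbose) {
      message(sprintf("[%s/%s] epoch %d  lr %.4g  loss %.4f",
                      config$variant, config$preset, epoch, lr, ep_loss))
    }
  }
  if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
  list(model = model, history = history, config = config)
}
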