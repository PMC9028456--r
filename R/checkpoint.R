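# Checkpoints: one serialized weights file plus a JSON sidecar describing
# the configuration, the embedding concatenation order and the class count,
# so a checkpoint is self-describing.

#' Save model weights and a JSON sidecar
#' @param model a `gpn_model`
#' @param path output file (an `.json` sidecar is written next to it)
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(model, path) {
  values <- lapply(model$params, function(p) p$value)
  buffers <- lapply(model$states, function(s)
    list(running_mean = s$running_mean, running_var = s$running_var))
  saveRDS(list(config = unclass(model$config), values = values,
               buffers = buffers), path)
  side <- list(
    config = unclass(model$config),
    num_train_classes = model$config$num_classes,
    embedding_dim = embedding_dim(model),
    embedding_layout = embedding_layout(model),
    num_parameters = sum(vapply(values, length, 0)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path checkpoint file
#' @return a `gpn_model` with restored weights and batch-norm statistics
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$config[c("backbone", "variant", "num_classes",
                                           "feat_dim", "stripes",
                                           "stripe_orientation", "n_stn",
                                           "stn_grid", "input_size")])
  model <- build_model(cfg)
  if (!setequal(names(model$params), names(ck$values))) {
    stop("checkpoint parameters do not match the rebuilt architecture")
  }
  for (nm in names(ck$values)) model$params[[nm]]$value <- ck$values[[nm]]
  for (nm in names(ck$buffers)) {
    model$states[[nm]]$running_mean <- ck$buffers[[nm]]$running_mean
    model$states[[nm]]$running_var <- ck$buffers[[nm]]$running_var
  }
  model
}
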