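# Model construction: parameter store, backbones honoring the two-map
# contract (stage-3 "mid" map and stride-1 stage-4 "high" map), and the
# reduce -> batch-norm -> classify heads shared by all branches.

new_param_store <- function() {
  env <- new.env(parent = emptyenv())
  env$params <- list()
  env$states <- list()
  env
}

add_conv <- function(model, name, kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  w <- array(stats::rnorm(kh * kw * cin * cout, sd = sd), dim = c(kh, kw, cin, cout))
  model$params[[paste0(name, ".w")]] <- ag_param(w, paste0(name, ".w"))
  model$params[[paste0(name, ".b")]] <- ag_param(numeric(cout), paste0(name, ".b"))
  invisible(model)
}

add_bn <- function(model, name, c) {
  model$params[[paste0(name, ".gamma")]] <- ag_param(rep(1, c), paste0(name, ".gamma"))
  model$params[[paste0(name, ".beta")]] <- ag_param(numeric(c), paste0(name, ".beta"))
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(c)
  st$running_var <- rep(1, c)
  model$states[[name]] <- st
  invisible(model)
}

add_linear <- function(model, name, din, dout, zero_init = FALSE) {
  w <- if (zero_init) matrix(0, dout, din)
       else matrix(stats::rnorm(dout * din, sd = sqrt(1 / din)), dout, din)
  model$params[[paste0(name, ".w")]] <- ag_param(w, paste0(name, ".w"))
  model$params[[paste0(name, ".b")]] <- ag_param(numeric(dout), paste0(name, ".b"))
  invisible(model)
}

p_ <- function(model, name) {
  p <- model$params[[name]]
  if (is.null(p)) stop("unknown parameter: ", name)
  p
}

apply_conv <- function(model, name, x, stride = 1L, pad = 0L) {
  op_conv2d(x, p_(model, paste0(name, ".w")), p_(model, paste0(name, ".b")),
            stride = stride, pad = pad)
}

apply_bn <- function(model, name, x, training) {
  op_batchnorm(x, p_(model, paste0(name, ".gamma")),
               p_(model, paste0(name, ".beta")),
               model$states[[name]], training = training)
}

apply_linear <- function(model, name, x) {
  op_linear(x, p_(model, paste0(name, ".w")), p_(model, paste0(name, ".b")))
}

cbnr <- function(model, name, x, stride, pad, training) {
  op_relu(apply_bn(model, paste0(name, ".bn"),
                   apply_conv(model, name, x, stride, pad), training))
}

#' Model configuration
#'
#' @param backbone `"resnet50"` (the reference backbone: 1024-channel stage-3
#'   map, 2048-channel stage-4 map with downsampling stride forced to 1) or
#'   `"tiny"`, a reduced-channel convolutional backbone honoring the same
#'   two-map contract for CPU-scale experiments (its head dimensions scale
#'   accordingly and are not the reference dimensions).
#' @param variant `"gpn"` (six-stripe Part branch) or `"gpn_st"` (four
#'   spatial-transformer attention modules in the Part branch).
#' @param num_classes number of training identities (classifier width).
#' @param feat_dim per-head feature width after the reduce layer; defaults to
#'   512 for resnet50 and 64 for tiny.
#' @param stripes number of uniform horizontal stripes in the GPN Part branch.
#' @param stripe_orientation `"horizontal"` (partition along image height,
#'   the part-based convention) or `"vertical"`.
#' @param n_stn number of spatial-transformer modules in the GPN-ST Part branch.
#' @param stn_grid output grid (height, width) of each sampled attention region.
#' @param input_size image size (height, width) the model expects.
#' @param pretrained must be `FALSE`: pretrained backbone weights are not
#'   bundled and cannot be fetched offline.
#' @return a `cowreid_config` list
#' @export
model_config <- function(backbone = c("tiny", "resnet50"),
                         variant = c("gpn", "gpn_st"),
                         num_classes,
                         feat_dim = NULL,
                         stripes = 6L,
                         stripe_orientation = c("horizontal", "vertical"),
                         n_stn = 4L,
                         stn_grid = c(6L, 6L),
                         input_size = NULL,
                         pretrained = FALSE) {
  backbone <- match.arg(backbone)
  variant <- match.arg(variant)
  stripe_orientation <- match.arg(stripe_orientation)
  if (isTRUE(pretrained)) {
    stop("pretrained backbone weights are unavailable offline; ",
         "build the model with pretrained = FALSE (random initialization)")
  }
  if (is.null(feat_dim)) feat_dim <- if (backbone == "resnet50") 512L else 64L
  if (is.null(input_size))
    input_size <- if (backbone == "resnet50") c(384L, 192L) else c(96L, 48L)
  ch <- if (backbone == "resnet50") {
    list(mid = 1024L, high = 2048L, loc_c = 128L, loc_h = 32L)
  } else {
    list(c1 = 16L, c2 = 32L, mid = 48L, high = 96L, loc_c = 16L, loc_h = 16L)
  }
  structure(list(backbone = backbone, variant = variant,
                 num_classes = as.integer(num_classes),
                 feat_dim = as.integer(feat_dim), stripes = as.integer(stripes),
                 stripe_orientation = stripe_orientation,
                 n_stn = as.integer(n_stn), stn_grid = as.integer(stn_grid),
                 input_size = as.integer(input_size),
                 channels = ch, pretrained = FALSE),
            class = "cowreid_config")
}

add_bottleneck <- function(model, name, cin, cmid, cout, stride) {
  add_conv(model, paste0(name, ".conv1"), 1, 1, cin, cmid)
  add_bn(model, paste0(name, ".conv1.bn"), cmid)
  add_conv(model, paste0(name, ".conv2"), 3, 3, cmid, cmid)
  add_bn(model, paste0(name, ".conv2.bn"), cmid)
  add_conv(model, paste0(name, ".conv3"), 1, 1, cmid, cout)
  add_bn(model, paste0(name, ".conv3.bn"), cout)
  if (cin != cout || stride != 1) {
    add_conv(model, paste0(name, ".down"), 1, 1, cin, cout)
    add_bn(model, paste0(name, ".down.bn"), cout)
  }
  invisible(model)
}

bottleneck_forward <- function(model, name, x, cin, cout, stride, training) {
  h <- op_relu(apply_bn(model, paste0(name, ".conv1.bn"),
                        apply_conv(model, paste0(name, ".conv1"), x), training))
  h <- op_relu(apply_bn(model, paste0(name, ".conv2.bn"),
                        apply_conv(model, paste0(name, ".conv2"), h,
                                   stride = stride, pad = 1L), training))
  h <- apply_bn(model, paste0(name, ".conv3.bn"),
                apply_conv(model, paste0(name, ".conv3"), h), training)
  sc <- if (cin != cout || stride != 1) {
    apply_bn(model, paste0(name, ".down.bn"),
             apply_conv(model, paste0(name, ".down"), x, stride = stride), training)
  } else x
  op_relu(op_add(h, sc))
}

.resnet50_stages <- list(
  layer1 = list(blocks = 3L, cmid = 64L, cout = 256L, stride = 1L),
  layer2 = list(blocks = 4L, cmid = 128L, cout = 512L, stride = 2L),
  layer3 = list(blocks = 6L, cmid = 256L, cout = 1024L, stride = 2L),
  # last-stride modification: stage-4 downsampling stride forced to 1 so the
  # final map keeps the stage-3 spatial resolution
  layer4 = list(blocks = 3L, cmid = 512L, cout = 2048L, stride = 1L)
)

build_backbone <- function(model) {
  cfg <- model$config
  if (cfg$backbone == "resnet50") {
    add_conv(model, "stem", 7, 7, 3, 64L)
    add_bn(model, "stem.bn", 64L)
    cin <- 64L
    for (ln in names(.resnet50_stages)) {
      st <- .resnet50_stages[[ln]]
      for (b in seq_len(st$blocks)) {
        add_bottleneck(model, paste0(ln, ".", b), cin, st$cmid, st$cout,
                       if (b == 1L) st$stride else 1L)
        cin <- st$cout
      }
    }
  } else {
    ch <- cfg$channels
    add_conv(model, "conv1", 3, 3, 3, ch$c1);   add_bn(model, "conv1.bn", ch$c1)
    add_conv(model, "conv2", 3, 3, ch$c1, ch$c2); add_bn(model, "conv2.bn", ch$c2)
    add_conv(model, "conv3", 3, 3, ch$c2, ch$mid); add_bn(model, "conv3.bn", ch$mid)
    add_conv(model, "conv4", 3, 3, ch$mid, ch$high); add_bn(model, "conv4.bn", ch$high)
  }
  invisible(model)
}

# Backbone forward pass returning the two-map contract:
# list(mid = stage-3 map [H3,W3,C_mid,N], high = stage-4 map with H4=H3, W4=W3)
backbone_forward <- function(model, x, training) {
  cfg <- model$config
  if (cfg$backbone == "resnet50") {
    h <- op_relu(apply_bn(model, "stem.bn",
                          apply_conv(model, "stem", x, stride = 2L, pad = 3L),
                          training))
    h <- op_maxpool(h, 3L, 2L, 1L)
    mid <- NULL
    cin <- 64L
    for (ln in names(.resnet50_stages)) {
      st <- .resnet50_stages[[ln]]
      for (b in seq_len(st$blocks)) {
        h <- bottleneck_forward(model, paste0(ln, ".", b), h, cin, st$cout,
                                if (b == 1L) st$stride else 1L, training)
        cin <- st$cout
      }
      if (ln == "layer3") mid <- h
    }
    list(mid = mid, high = h)
  } else {
    h <- cbnr(model, "conv1", x, 2L, 1L, training)
    h <- cbnr(model, "conv2", h, 2L, 1L, training)
    mid <- cbnr(model, "conv3", h, 2L, 1L, training)
    high <- cbnr(model, "conv4", mid, 1L, 1L, training)
    list(mid = mid, high = high)
  }
}

add_head <- function(model, name, in_dim) {
  cfg <- model$config
  add_linear(model, paste0("head_", name, ".reduce"), in_dim, cfg$feat_dim)
  add_bn(model, paste0("head_", name, ".bn"), cfg$feat_dim)
  add_linear(model, paste0("head_", name, ".classify"), cfg$feat_dim, cfg$num_classes)
  invisible(model)
}

# Three-layer classifier head: linear reduce to feat_dim, batch norm, linear
# classifier. The post-BN vector is the test-time feature ("*_Down");
# classification logits are computed from it.
head_forward <- function(model, name, x, training) {
  feat <- apply_bn(model, paste0("head_", name, ".bn"),
                   apply_linear(model, paste0("head_", name, ".reduce"), x),
                   training)
  logits <- apply_linear(model, paste0("head_", name, ".classify"), feat)
  list(feat = feat, logits = logits)
}

#' Build a GPN or GPN-ST model
#'
#' Instantiates the backbone, the Global and Middle branch heads, and either
#' six stripe heads (GPN) or four spatial-transformer modules with their heads
#' (GPN-ST). Weights are randomly initialized (He initialization for
#' convolutions) from the current RNG state; seed the RNG for reproducible
#' builds.
#'
#' @param config a [model_config()] list
#' @return a `gpn_model` object
#' @examples
#' set.seed(1)
#' m <- build_model(model_config("tiny", "gpn", num_classes = 5))
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "cowreid_config"))
  model <- new_param_store()
  model$config <- config
  class(model) <- c("gpn_model", "environment")
  build_backbone(model)
  ch <- config$channels
  add_head(model, "G", ch$high)
  add_head(model, "M", ch$mid)
  if (config$variant == "gpn") {
    for (k in seq_len(config$stripes)) add_head(model, paste0("P", k), ch$high)
  } else {
    for (m in seq_len(config$n_stn)) {
      add_stn_module(model, m, ch)
      add_head(model, paste0("ST", m), ch$high)
    }
  }
  model
}

#' @export
print.gpn_model <- function(x, ...) {
  cfg <- x$config
  npar <- sum(vapply(x$params, function(p) length(p$value), 0))
  cat(sprintf("<gpn_model> variant=%s backbone=%s classes=%d feat_dim=%d params=%s\n",
              cfg$variant, cfg$backbone, cfg$num_classes, cfg$feat_dim,
              format(npar, big.mark = ",")))
  cat(sprintf("  input %dx%d (HxW); test embedding %d-d\n",
              cfg$input_size[1], cfg$input_size[2], embedding_dim(x)))
  invisible(x)
}

#' Test-time embedding dimensionality of a model
#' @param model a `gpn_model`
#' @return integer: heads x feat_dim (8 heads for GPN, 6 for GPN-ST)
#' @export
embedding_dim <- function(model) {
  cfg <- model$config
  nheads <- if (cfg$variant == "gpn") 2L + cfg$stripes else 2L + cfg$n_stn
  nheads * cfg$feat_dim
}

model_params <- function(model) model$params
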