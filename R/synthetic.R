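# Deterministic synthetic cattle-face imagery.
#
# Every identity gets a two-tone Voronoi coat pattern on a shared face-shaped
# canvas with slightly jittered landmarks (eyes, ears, muzzle): identities
# share the global layout (high inter-identity similarity) while the patch
# geometry differs (the discriminative signal). Per-image nuisances emulate
# capture conditions: viewpoint shear, illumination scaling, Gaussian blur,
# partial occlusion and sensor noise. Everything is a pure function of the
# seeds, so datasets are bitwise reproducible.

mix_seed <- function(...) {
  s <- 0
  for (v in c(...)) s <- (s * 69069 + as.numeric(v) + 101) %% 2147483647
  as.integer(s)
}

#' Nuisance configuration for the synthetic renderer
#' @param brightness multiplicative illumination range
#' @param blur_sigma Gaussian blur sigma range in pixels
#' @param shear horizontal shear strength for left/right views
#' @param occlusion_prob probability of a partial occlusion rectangle
#' @param occlusion_area_max maximum occluded area fraction (capped at 0.3 so
#'   the identity signal always survives)
#' @param noise_sd additive Gaussian pixel noise sd
#' @return a `synth_config` list
#' @export
synth_config <- function(brightness = c(0.6, 1.4), blur_sigma = c(0, 1.5),
                         shear = 0.25, occlusion_prob = 0.2,
                         occlusion_area_max = 0.3, noise_sd = 0.02) {
  stopifnot(occlusion_area_max <= 0.3)
  structure(list(brightness = brightness, blur_sigma = blur_sigma,
                 shear = shear, occlusion_prob = occlusion_prob,
                 occlusion_area_max = occlusion_area_max,
                 noise_sd = noise_sd), class = "synth_config")
}

#' Identity template: coat pattern and landmark jitter
#'
#' Fully determined by `(identity, global_seed)`.
#' @param identity integer identity
#' @param global_seed dataset-level seed
#' @param cells number of Voronoi cells in the coat pattern
#' @return an `identity_template` list
#' @export
identity_template <- function(identity, global_seed, cells = 12L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(mix_seed(global_seed, identity, 1))
  centers <- cbind(stats::runif(cells, 0.05, 0.95),
                   stats::runif(cells, 0.05, 0.95))
  colors <- stats::rbinom(cells, 1, 0.5)
  if (all(colors == colors[1])) colors[1] <- 1 - colors[1]
  structure(list(identity = as.integer(identity), cells = cells,
                 centers = centers, colors = colors,
                 eye_jitter = stats::runif(4, -0.035, 0.035),
                 muzzle_jitter = stats::runif(2, -0.03, 0.03),
                 muzzle_tone = stats::runif(1, 0.55, 0.75),
                 ear_jitter = stats::runif(2, -0.02, 0.02)),
            class = "identity_template")
}

#' Draw nuisance parameters from the current RNG stream
#' @param config a [synth_config()]
#' @return a `nuisance_params` list (view angle, brightness, blur, occlusion,
#'   noise); `neutral_nuisance()` gives the all-neutral setting
#' @export
draw_nuisance <- function(config = synth_config()) {
  view <- sample(c("left", "frontal", "right"), 1)
  occl <- NULL
  if (stats::runif(1) < config$occlusion_prob) {
    occl <- list(area = stats::runif(1, 0.05, config$occlusion_area_max),
                 aspect = stats::runif(1, 0.5, 2),
                 cx = stats::runif(1, 0.2, 0.8), cy = stats::runif(1, 0.2, 0.8))
  }
  structure(list(view = view,
                 brightness = stats::runif(1, config$brightness[1], config$brightness[2]),
                 blur_sigma = stats::runif(1, config$blur_sigma[1], config$blur_sigma[2]),
                 occlusion = occl,
                 noise_sd = config$noise_sd,
                 shear = config$shear), class = "nuisance_params")
}

#' @rdname draw_nuisance
#' @export
neutral_nuisance <- function() {
  structure(list(view = "frontal", brightness = 1, blur_sigma = 0,
                 occlusion = NULL, noise_sd = 0, shear = 0.25),
            class = "nuisance_params")
}

ellipse_mask <- function(u, v, cx, cy, ru, rv) {
  ((u - cx) / ru)^2 + ((v - cy) / rv)^2 <= 1
}

# Canonical frontal face raster for a template, [H, W, 3] in [0, 1]
canonical_face <- function(template, size) {
  H <- size[1]; W <- size[2]
  u <- matrix(rep(seq(0, 1, length.out = W), each = H), H, W)
  v <- matrix(rep(seq(0, 1, length.out = H), W), H, W)
  gray <- matrix(0.55, H, W)
  # ears behind the face outline
  ej <- template$ear_jitter
  ears <- ellipse_mask(u, v, 0.10 + ej[1], 0.10, 0.11, 0.08) |
          ellipse_mask(u, v, 0.90 + ej[2], 0.10, 0.11, 0.08)
  gray[ears] <- 0.25
  # two-tone Voronoi coat inside the face ellipse
  face <- ellipse_mask(u, v, 0.5, 0.55, 0.44, 0.42)
  d2 <- matrix(Inf, H * W, template$cells)
  uv <- cbind(as.vector(u), as.vector(v))
  for (k in seq_len(template$cells)) {
    d2[, k] <- (uv[, 1] - template$centers[k, 1])^2 +
               (uv[, 2] - template$centers[k, 2])^2
  }
  lab <- max.col(-d2, ties.method = "first")
  coat <- ifelse(template$colors[lab] == 1, 0.88, 0.12)
  gray[face] <- coat[as.vector(face)]
  img <- array(rep(gray, 3L), dim = c(H, W, 3L))
  # eyes
  e <- template$eye_jitter
  eyes <- ellipse_mask(u, v, 0.32 + e[1], 0.40 + e[2], 0.045, 0.04) |
          ellipse_mask(u, v, 0.68 + e[3], 0.40 + e[4], 0.045, 0.04)
  for (ch in 1:3) { pl <- img[, , ch]; pl[eyes] <- 0.05; img[, , ch] <- pl }
  # muzzle with a warm tint
  mj <- template$muzzle_jitter
  muz <- ellipse_mask(u, v, 0.5 + mj[1], 0.82 + mj[2], 0.17, 0.10)
  tone <- template$muzzle_tone
  tint <- c(0.10, 0.00, -0.06)
  for (ch in 1:3) {
    pl <- img[, , ch]; pl[muz] <- min(max(tone + tint[ch], 0), 1)
    img[, , ch] <- pl
  }
  img
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0.05) return(img)
  band <- function(n) {
    K <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = sigma)
    K[abs(outer(seq_len(n), seq_len(n), "-")) > ceiling(3 * sigma)] <- 0
    K / rowSums(K)
  }
  KH <- band(dim(img)[1]); KW <- band(dim(img)[2])
  for (ch in 1:3) img[, , ch] <- KH %*% img[, , ch] %*% t(KW)
  img
}

#' Render one synthetic face image
#'
#' Canonical identity raster, then viewpoint shear (left/right views shear
#' the face horizontally), illumination scaling, Gaussian blur, optional
#' partial occlusion (area capped so the coat pattern survives), and additive
#' noise. The all-neutral nuisance returns the identity's canonical frontal
#' face.
#'
#' @param template an [identity_template()]
#' @param nuisance a nuisance parameter list ([draw_nuisance()] /
#'   [neutral_nuisance()])
#' @param size image (height, width)
#' @return `[H, W, 3]` array in `[0, 1]`
#' @export
render_face <- function(template, nuisance, size = c(96L, 48L)) {
  img <- canonical_face(template, size)
  s <- switch(nuisance$view, left = -nuisance$shear, frontal = 0,
              right = nuisance$shear)
  if (s != 0) {
    x <- array(img, dim = c(dim(img), 1L))
    A <- matrix(c(1, 0, s, 1, 0, 0), 2, 3)  # xs = xo + s*yo
    img <- array(affine_warp_cpp(x, A, dim(img)[1], dim(img)[2], TRUE),
                 dim = dim(img))
  }
  img <- gaussian_blur(img, nuisance$blur_sigma)
  img <- img * nuisance$brightness
  if (!is.null(nuisance$occlusion)) {
    oc <- nuisance$occlusion
    H <- dim(img)[1]; W <- dim(img)[2]
    eh <- max(1, round(sqrt(oc$area * oc$aspect) * H))
    ew <- max(1, round(sqrt(oc$area / oc$aspect) * W))
    y0 <- max(1, min(H - eh + 1, round(oc$cy * H - eh / 2)))
    x0 <- max(1, min(W - ew + 1, round(oc$cx * W - ew / 2)))
    img[y0:(y0 + eh - 1), x0:(x0 + ew - 1), ] <-
      0.45 + stats::runif(eh * ew * 3, -0.05, 0.05)
  }
  if (nuisance$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), sd = nuisance$noise_sd)
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic re-identification dataset on disk
#'
#' Writes the `<split>/<identity>/<index>.png` layout consumed by
#' [load_dataset()], plus `manifest.tsv` and `split.json`. Train identities
#' are `0 .. num_train_ids-1`; test identities continue from `num_train_ids`
#' (disjoint, open set). Output is bitwise identical across runs with equal
#' arguments.
#'
#' @param out_dir output directory (must be empty unless `overwrite`)
#' @param num_train_ids,num_test_ids identity counts
#' @param imgs_per_train_id training images per identity
#' @param query_per_id,gallery_per_id test images per identity
#' @param image_size (height, width) of generated images
#' @param global_seed master seed; every image derives its own stream from it
#' @param cells Voronoi cells per coat pattern
#' @param nuisance a [synth_config()]
#' @param overwrite allow writing into a non-empty directory
#' @return the loaded `reid_dataset`
#' @export
generate_dataset <- function(out_dir,
                             num_train_ids = 20L, num_test_ids = 10L,
                             imgs_per_train_id = 50L,
                             query_per_id = 10L, gallery_per_id = 20L,
                             image_size = c(96L, 48L), global_seed = 7L,
                             cells = 12L, nuisance = synth_config(),
                             overwrite = FALSE) {
  stopifnot(num_train_ids >= 1, num_test_ids >= 1, imgs_per_train_id >= 1,
            query_per_id >= 1, gallery_per_id >= 1)
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite) {
    stop("output directory exists and is not empty: ", out_dir,
         " (use overwrite = TRUE)")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  write_imgs <- function(id, split, n, split_code) {
    tpl <- identity_template(id, global_seed, cells)
    dir.create(file.path(out_dir, split, sprintf("%04d", id)),
               recursive = TRUE, showWarnings = FALSE)
    vapply(seq_len(n), function(i) {
      set.seed(mix_seed(global_seed, id, split_code, i))
      nui <- draw_nuisance(nuisance)
      img <- render_face(tpl, nui, image_size)
      path <- file.path(out_dir, split, sprintf("%04d", id),
                        sprintf("%03d.png", i))
      png::writePNG(img, path)
      path
    }, "")
  }
  recs <- list()
  for (id in seq_len(num_train_ids) - 1L) {
    p <- write_imgs(id, "train", imgs_per_train_id, 1L)
    recs[[length(recs) + 1L]] <- data.frame(path = p, identity = id, split = "train")
  }
  for (id in num_train_ids + seq_len(num_test_ids) - 1L) {
    p <- write_imgs(id, "query", query_per_id, 2L)
    recs[[length(recs) + 1L]] <- data.frame(path = p, identity = id, split = "query")
    p <- write_imgs(id, "gallery", gallery_per_id, 3L)
    recs[[length(recs) + 1L]] <- data.frame(path = p, identity = id, split = "gallery")
  }
  df <- do.call(rbind, recs)
  man <- df
  man$path <- substring(man$path, nchar(out_dir) + 2L)
  utils::write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ds <- load_dataset(out_dir)
  write_split_descriptor(ds, file.path(out_dir, "split.json"), global_seed)
  ds
}
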