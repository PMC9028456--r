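# Identity-labeled image collections for open-set re-identification:
# loading, the train / query / gallery partition, capped gallery views,
# the identity-balanced PK batch sampler, and training augmentation.

SPLITS <- c("train", "query", "gallery")

#' Read an image file as an `[H, W, 3]` array in `[0, 1]`
#' @param path PNG file path
#' @return numeric array `[H, W, 3]`
#' @export
load_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

new_reid_dataset <- function(records, source) {
  records$split <- as.character(records$split)
  records$identity <- as.integer(records$identity)
  train_ids <- sort(unique(records$identity[records$split == "train"]))
  test_ids <- sort(unique(records$identity[records$split != "train"]))
  if (length(overlap <- intersect(train_ids, test_ids))) {
    stop("open-set violation: identities present in both train and ",
         "query/gallery: ", paste(utils::head(overlap, 10), collapse = ", "))
  }
  qi <- unique(records$identity[records$split == "query"])
  gi <- unique(records$identity[records$split == "gallery"])
  if (length(nog <- setdiff(qi, gi))) {
    stop("query identities without any gallery image: ",
         paste(utils::head(nog, 10), collapse = ", "))
  }
  # dense 0-based class indices, assigned separately within the train group
  # and the test (query+gallery) group
  records$class_index <- ifelse(
    records$split == "train",
    match(records$identity, train_ids) - 1L,
    match(records$identity, test_ids) - 1L)
  structure(list(records = records,
                 num_train_classes = length(train_ids),
                 num_test_ids = length(test_ids),
                 source = source),
            class = "reid_dataset")
}

#' Load an identity-labeled re-identification dataset
#'
#' Accepts either a directory laid out as `<split>/<identity>/<image>.png`
#' with splits `train`, `query`, `gallery`, or a TSV manifest with columns
#' `path`, `identity`, `split` (paths relative to the manifest's directory or
#' absolute). Identities are remapped to dense 0-based class indices per
#' split group. The open-set invariants are enforced: train and test identity
#' sets must be disjoint, and every query identity needs at least one gallery
#' image.
#'
#' @param root_or_manifest directory or manifest file path
#' @return a `reid_dataset`
#' @export
load_dataset <- function(root_or_manifest) {
  if (dir.exists(root_or_manifest)) {
    root <- root_or_manifest
    recs <- list()
    for (sp in SPLITS) {
      spdir <- file.path(root, sp)
      if (!dir.exists(spdir)) next
      for (iddir in list.dirs(spdir, recursive = FALSE)) {
        id <- suppressWarnings(as.integer(basename(iddir)))
        if (is.na(id)) stop("identity folder name is not an integer: ", iddir)
        files <- sort(list.files(iddir, pattern = "\\.(png|PNG)$",
                                 full.names = TRUE))
        if (length(files)) {
          recs[[length(recs) + 1L]] <-
            data.frame(path = files, identity = id, split = sp)
        }
      }
    }
    if (!length(recs)) stop("no images found under ", root)
    df <- do.call(rbind, recs)
  } else if (file.exists(root_or_manifest)) {
    df <- utils::read.delim(root_or_manifest, stringsAsFactors = FALSE)
    if (!all(c("path", "identity", "split") %in% names(df))) {
      stop("manifest must have columns path, identity, split")
    }
    rel <- !file.exists(df$path)
    df$path[rel] <- file.path(dirname(root_or_manifest), df$path[rel])
  } else {
    stop("no such directory or manifest: ", root_or_manifest)
  }
  if (!all(df$split %in% SPLITS)) {
    stop("split must be one of ", paste(SPLITS, collapse = ", "))
  }
  if (any(missing <- !file.exists(df$path))) {
    stop("missing image files:\n  ",
         paste(utils::head(df$path[missing], 20), collapse = "\n  "))
  }
  new_reid_dataset(df, root_or_manifest)
}

#' @export
print.reid_dataset <- function(x, ...) {
  tab <- table(x$records$split)
  cat(sprintf("<reid_dataset> %d images: %s\n", nrow(x$records),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  %d train identities, %d test identities (open set)\n",
              x$num_train_classes, x$num_test_ids))
  invisible(x)
}

#' Capped per-identity gallery view
#'
#' Deterministic pseudo-random sample of at most `cap_n` gallery images per
#' identity (all of them if fewer are available); identities are processed in
#' sorted order so the selection depends only on `seed`.
#'
#' @param dataset a `reid_dataset`
#' @param cap_n per-identity cap (>= 1), or `"all"`
#' @param seed integer selection seed (recorded for reproducibility)
#' @return gallery records data.frame with attributes `cap` and `seed`
#' @export
make_gallery_view <- function(dataset, cap_n, seed = 1L) {
  gal <- dataset$records[dataset$records$split == "gallery", , drop = FALSE]
  if (identical(cap_n, "all")) {
    attr(gal, "cap") <- "all"; attr(gal, "seed") <- seed
    return(gal)
  }
  if (!is.numeric(cap_n) || cap_n < 1) stop("cap_n must be >= 1 or \"all\"")
  keep <- integer(0)
  rows <- seq_len(nrow(gal))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  for (id in sort(unique(gal$identity))) {
    ridx <- rows[gal$identity == id]
    k <- min(length(ridx), as.integer(cap_n))
    keep <- c(keep, if (length(ridx) == 1L) ridx else sample(ridx, k))
  }
  out <- gal[sort(keep), , drop = FALSE]
  attr(out, "cap") <- as.integer(cap_n)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' PK sampler configuration
#' @param p identities per batch (default 8)
#' @param k images per identity (default 4); identities with fewer than `k`
#'   images are sampled with replacement
#' @return a `sampler_config` list with `batch_size = p * k`
#' @export
sampler_config <- function(p = 8L, k = 4L) {
  stopifnot(p >= 2, k >= 1)
  structure(list(p = as.integer(p), k = as.integer(k),
                 batch_size = as.integer(p * k)), class = "sampler_config")
}

#' Identity-balanced PK batches over the training split
#'
#' Emits one epoch of batches; every batch holds exactly `p` distinct
#' identities with `k` images each. The number of batches is
#' `ceiling(n_train / (p * k))`. Identities are drawn without replacement
#' within a batch; images without replacement per identity when possible.
#'
#' @param dataset a `reid_dataset`
#' @param config a [sampler_config()]
#' @param seed integer seed for this epoch's draws
#' @return list of integer index vectors into `dataset$records`
#' @export
pk_batches <- function(dataset, config = sampler_config(), seed = 1L) {
  tr <- which(dataset$records$split == "train")
  ids <- unique(dataset$records$identity[tr])
  if (length(ids) < config$p) {
    stop(sprintf("PK sampler needs at least P=%d train identities, have %d",
                 config$p, length(ids)))
  }
  by_id <- split(tr, dataset$records$identity[tr])
  n_batches <- ceiling(length(tr) / config$batch_size)
  set.seed(seed)
  lapply(seq_len(n_batches), function(b) {
    chosen <- sample(as.character(ids), config$p)
    unlist(lapply(chosen, function(id) {
      pool <- by_id[[id]]
      if (length(pool) >= config$k) {
        if (length(pool) == config$k) pool else sample(pool, config$k)
      } else {
        pool[sample.int(length(pool), config$k, replace = TRUE)]
      }
    }), use.names = FALSE)
  })
}

#' Augmentation configuration
#'
#' Defaults follow common re-identification practice: resize to 384x192
#' (height x width), horizontal flip with probability 0.5, random erasing
#' with probability 0.5 replacing a rectangle of 2-40% of the image area and
#' aspect ratio in `[0.3, 3.3]` with per-pixel uniform noise.
#'
#' @param resize target (height, width) in pixels
#' @param hflip_prob horizontal flip probability
#' @param erase_prob random-erasing probability
#' @param erase_area area fraction range of the erased rectangle
#' @param erase_aspect aspect-ratio (h/w) range of the erased rectangle
#' @return an `augment_config` list
#' @export
augment_config <- function(resize = c(384L, 192L), hflip_prob = 0.5,
                           erase_prob = 0.5, erase_area = c(0.02, 0.4),
                           erase_aspect = c(0.3, 3.3)) {
  structure(list(resize = as.integer(resize), hflip_prob = hflip_prob,
                 erase_prob = erase_prob, erase_area = erase_area,
                 erase_aspect = erase_aspect), class = "augment_config")
}

#' Bilinear image resize
#' @param image `[H, W, C]` array
#' @param size target (height, width)
#' @return resized `[size[1], size[2], C]` array
#' @export
resize_image <- function(image, size) {
  d <- dim(image)
  x <- array(image, dim = c(d[1], d[2], d[3], 1L))
  A <- matrix(c(1, 0, 0, 1, 0, 0), 2, 3)
  y <- affine_warp_cpp(x, A, as.integer(size[1]), as.integer(size[2]), TRUE)
  array(y, dim = c(size[1], size[2], d[3]))
}

#' Training-time augmentation
#'
#' Resize to the configured size, horizontal flip with probability
#' `hflip_prob` (an exact column reversal, so flipping twice restores the
#' resized image), then random erasing with probability `erase_prob`.
#' Randomness comes from the R RNG; seed it for determinism.
#'
#' @param image `[H, W, 3]` array in `[0, 1]`
#' @param config an [augment_config()]
#' @return augmented `[resize[1], resize[2], 3]` array
#' @export
augment_image <- function(image, config = augment_config()) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("augment_image expects an RGB [H, W, 3] array")
  }
  out <- if (all(dim(image)[1:2] == config$resize)) image
         else resize_image(image, config$resize)
  if (config$hflip_prob > 0 && stats::runif(1) < config$hflip_prob) {
    out <- out[, ncol(out):1, , drop = FALSE]
  }
  if (config$erase_prob > 0 && stats::runif(1) < config$erase_prob) {
    H <- dim(out)[1]; W <- dim(out)[2]
    for (try in 1:100) {
      area <- stats::runif(1, config$erase_area[1], config$erase_area[2]) * H * W
      aspect <- exp(stats::runif(1, log(config$erase_aspect[1]),
                                 log(config$erase_aspect[2])))
      eh <- round(sqrt(area * aspect)); ew <- round(sqrt(area / aspect))
      if (eh >= 1 && ew >= 1 && eh <= H && ew <= W) {
        y0 <- sample.int(H - eh + 1L, 1L); x0 <- sample.int(W - ew + 1L, 1L)
        out[y0:(y0 + eh - 1L), x0:(x0 + ew - 1L), ] <-
          stats::runif(eh * ew * 3L)
        break
      }
    }
  }
  out
}

#' Write a JSON split descriptor beside a dataset
#' @param dataset a `reid_dataset`
#' @param path output JSON path (default `split.json` beside the source)
#' @param gallery_seed gallery-view selection seed to record
#' @return the path, invisibly
#' @export
write_split_descriptor <- function(dataset, path = NULL, gallery_seed = 1L) {
  if (is.null(path)) path <- file.path(dataset$source, "split.json")
  counts <- as.list(table(dataset$records$split))
  desc <- list(
    num_images = nrow(dataset$records),
    counts = counts,
    num_train_identities = dataset$num_train_classes,
    num_test_identities = dataset$num_test_ids,
    gallery_view_seed = gallery_seed)
  jsonlite::write_json(desc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
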