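# Dataset manifests, image decoding/preprocessing and model checkpoints.

#' Load a dataset manifest
#'
#' Reads a CSV manifest with columns `path`, `bdi2_score` and `split`,
#' validates it (scores in \[0, 63\], known split labels, files resolvable
#' against `base_dir`) and returns it as a tibble with an extra
#' `abs_path` column. Errors name the first offending row.
#'
#' @param path Path to the manifest CSV.
#' @param base_dir Directory image paths are relative to (default: the
#'   manifest's directory).
#' @param check_files Verify that every image file exists.
#' @return Tibble with `path`, `bdi2_score`, `split`, `abs_path`.
#' @export
load_manifest <- function(path, base_dir = dirname(path),
                          check_files = TRUE) {
  if (!file.exists(path))
    abort(sprintf("manifest '%s' does not exist", path))
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("path", "bdi2_score", "split")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0)
    abort(sprintf("manifest is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  if (nrow(m) == 0) abort("manifest contains no rows")
  if (!is.numeric(m$bdi2_score))
    abort("manifest column bdi2_score must be numeric")
  bad <- which(!is.finite(m$bdi2_score) | m$bdi2_score < 0 |
               m$bdi2_score > 63)
  if (length(bad) > 0)
    abort(sprintf("manifest row %d: bdi2_score %s is outside [0, 63]",
                  bad[1], format(m$bdi2_score[bad[1]])))
  bad <- which(!m$split %in% c("train", "dev", "test"))
  if (length(bad) > 0)
    abort(sprintf(
      "manifest row %d: split '%s' is not one of train/dev/test",
      bad[1], m$split[bad[1]]))
  m$abs_path <- ifelse(grepl("^(/|[A-Za-z]:)", m$path), m$path,
                       file.path(base_dir, m$path))
  if (check_files) {
    bad <- which(!file.exists(m$abs_path))
    if (length(bad) > 0)
      abort(sprintf("manifest row %d: image file '%s' does not exist",
                    bad[1], m$abs_path[bad[1]]))
  }
  as_tibble(m)
}

#' Decode and preprocess one image
#'
#' Decodes an image file, converts it to three channels (grayscale is
#' replicated, an alpha channel is dropped), resizes it bilinearly to
#' `size` x `size` and returns intensities in \[0, 1\].
#'
#' @param path Image file path (any format EBImage can decode).
#' @param size Target side length in pixels.
#' @return `(size, size, 3)` array in \[0, 1\] (rows = image rows).
#' @export
preprocess_image <- function(path, size = 224L) {
  if (!file.exists(path))
    abort(sprintf("image '%s' does not exist", path))
  img <- EBImage::readImage(path)
  img <- EBImage::resize(img, w = size, h = size)
  a <- EBImage::imageData(img)                   # (x, y[, c])
  if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1L)
  if (dim(a)[3] >= 4) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1) a <- a[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(a)[3] == 2)
    abort(sprintf("image '%s' has 2 channels; cannot interpret", path))
  a <- aperm(a, c(2, 1, 3))                      # -> (H, W, C)
  pmin(pmax(a, 0), 1)
}

# Stack images listed in a manifest slice into an (H, W, 3, N) batch.
load_image_batch <- function(paths, size = 224L) {
  n <- length(paths)
  out <- array(0, c(size, size, 3L, n))
  for (i in seq_len(n)) out[, , , i] <- preprocess_image(paths[i], size)
  out
}

# ---- checkpoints -------------------------------------------------------------

# trainable fields and batch-norm buffers of an R-side layer
layer_state <- function(l) {
  out <- list()
  for (f in c("w", "b", "gamma", "beta", "run_mean", "run_var"))
    if (!is.null(l[[f]])) out[[f]] <- l[[f]]
  out
}

set_layer_state <- function(l, st) {
  for (f in names(st)) assign(f, st[[f]], envir = l)
  invisible(l)
}

# Pull every trainable tensor (and batch-norm buffer) into a plain list.
model_state <- function(model) {
  st <- list(config = model$config,
             layers = lapply(collect_layers(model), layer_state),
             backbone = fb_weights(model$backbone))
  if (inherits(model$dff, "hmhn_fast_dff"))
    st$dff <- dff_weights(model$dff)
  if (!is.null(model$mab))
    st$spatial <- lapply(model$mab$heads, function(hd)
      if (inherits(hd$spatial, "hmhn_fast_stack")) cs_weights(hd$spatial))
  st
}

set_model_state <- function(model, st) {
  layers <- collect_layers(model)
  if (length(layers) != length(st$layers))
    abort("checkpoint layer count does not match the model")
  for (i in seq_along(layers)) set_layer_state(layers[[i]], st$layers[[i]])
  fb_set_weights(model$backbone, st$backbone)
  if (!is.null(st$dff)) dff_set_weights(model$dff, st$dff)
  if (!is.null(st$spatial))
    for (i in seq_along(model$mab$heads))
      if (!is.null(st$spatial[[i]]))
        cs_set_weights(model$mab$heads[[i]]$spatial, st$spatial[[i]])
  invisible(model)
}

#' Save model weights to a checkpoint file
#'
#' Stores the configuration, every trainable tensor and the batch-norm
#' running statistics. Optimiser state is not saved; a loaded model is
#' ready for inference or fresh fine-tuning.
#'
#' @param model An `hmhn_model`.
#' @param path Destination file (RDS format).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model_state(model), path)
  invisible(path)
}

#' Load a model from a checkpoint file
#'
#' Rebuilds the network from the stored configuration and restores all
#' weights and batch-norm statistics.
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return An `hmhn_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    abort(sprintf("checkpoint '%s' does not exist", path))
  st <- readRDS(path)
  if (!is.list(st) || is.null(st$config) || is.null(st$layers))
    abort(sprintf("'%s' is not an hmhn checkpoint", path))
  model <- hmhn_model(st$config)
  set_model_state(model, st)
  model
}
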