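# Training loop: seeded AdamW on L_sum = L_mse + L_att with a dev-MAE
# plateau learning-rate schedule, per-epoch logging and best-epoch weight
# restoration.

# Predict scores for an (H, W, C, N) batch in chunks (eval mode).
predict_scores <- function(model, x, batch_size = 16L) {
  n <- dim(x)[4]
  out <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx] <- model_predict(model, x[, , , idx, drop = FALSE])
  }
  out
}

# Re-estimate batch-norm running statistics under the current (frozen)
# weights with forward-only passes in train mode. The exponential moving
# averages otherwise lag the rapidly changing weights early in training,
# so eval-mode activations see a shifted distribution and predictions
# drift ("precise BN" recalibration, as in stochastic weight averaging).
bn_recalibrate <- function(model, x, batch_size, passes = 2L) {
  n <- dim(x)[4]
  for (p in seq_len(passes))
    for (start in seq(1, n, by = batch_size)) {
      idx <- start:min(start + batch_size - 1L, n)
      model_forward(model, x[, , , idx, drop = FALSE], train = TRUE)
    }
  invisible(model)
}

# Gradients of the partition loss on the k head maps, as a list of
# (H, W, C, N) arrays (NULL when the loss is disabled or k < 2).
partition_grads <- function(c_maps, map_dim, eps) {
  k <- length(c_maps)
  if (k < 2) return(NULL)
  pooled <- pool_heads(c_maps)
  grad <- partition_loss_grad(pooled, eps)
  lapply(seq_len(k), function(i)
    gap_backward(grad[, , i], map_dim))
}

#' Train the network on a manifest of images
#'
#' Runs seeded mini-batch AdamW on the joint objective
#' `L_sum = L_mse + L_att` (the partition term only when
#' `config$use_partition` is `TRUE` and the cross-attention stage is
#' enabled). After every epoch the batch-norm running statistics are
#' recalibrated over the train split with frozen weights, then the model
#' is scored on the dev split; the
#' learning rate decays by `config$lr_decay_factor` when the dev MAE
#' plateaus for `config$plateau_patience` epochs, and the weights of the
#' best dev-MAE epoch are restored at the end. All images are decoded and
#' resized to `config$image_size` up front.
#'
#' @param manifest A manifest tibble from [load_manifest()] or
#'   [generate_dataset()], or a path to a manifest CSV. Must contain a
#'   `train` split; `dev` is used for model selection (falling back to
#'   `test` if absent).
#' @param config An [hmhn_config()].
#' @param base_dir Directory image paths are relative to (only needed when
#'   the manifest lacks an `abs_path` column).
#' @param verbose Print one line per epoch.
#' @return An object of class `hmhn_fit`: the trained model, the training
#'   `history` tibble (epoch, losses, dev metrics, learning rate) and the
#'   selected `best_epoch`.
#' @export
hmhn_train <- function(manifest, config = hmhn_config(), base_dir = ".",
                       verbose = TRUE) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  if (!all(c("bdi2_score", "split") %in% names(manifest)))
    abort("manifest must have bdi2_score and split columns")
  if (!"abs_path" %in% names(manifest))
    manifest$abs_path <- file.path(base_dir, manifest$path)
  tr <- manifest[manifest$split == "train", ]
  dv <- manifest[manifest$split == "dev", ]
  if (nrow(dv) == 0) dv <- manifest[manifest$split == "test", ]
  if (nrow(tr) == 0) abort("manifest has no train rows")

  sz <- config$image_size
  x_tr <- load_image_batch(tr$abs_path, sz)
  y_tr <- tr$bdi2_score
  x_dv <- if (nrow(dv) > 0) load_image_batch(dv$abs_path, sz)
  y_dv <- dv$bdi2_score

  model <- hmhn_model(config)
  set.seed(config$seed + 1L)
  sched <- plateau_scheduler(config$lr, config$lr_decay_factor,
                             config$plateau_patience)
  n <- length(y_tr)
  bs <- min(config$batch_size, n)
  use_att <- config$use_partition && config$use_mab && config$num_heads >= 2
  t_step <- 0L
  history <- vector("list", config$epochs)
  best <- list(mae = Inf, epoch = 0L, state = NULL)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    sums <- c(l_mse = 0, l_att = 0, l_sum = 0)
    nb <- 0L
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      xb <- x_tr[, , , idx, drop = FALSE]
      yb <- y_tr[idx]
      zero_grads(model)
      fwd <- model_forward(model, xb, train = TRUE)
      lb <- total_loss(fwd$pred, yb,
                       heads = if (use_att) fwd$c_maps,
                       eps = config$loss_eps)
      if (!is.finite(lb$l_sum))
        abort(sprintf("non-finite loss at epoch %d (L_sum = %g)",
                      epoch, lb$l_sum))
      dpred <- 2 * (fwd$pred - yb) / length(yb)
      datt <- if (use_att)
        partition_grads(fwd$c_maps, dim(fwd$c_maps[[1]]), config$loss_eps)
      model_backward(model, dpred, datt)
      t_step <- t_step + 1L
      optimizer_step(model, sched$lr, t_step,
                     wd = config$weight_decay)
      sums <- sums + c(lb$l_mse, lb$l_att, lb$l_sum)
      nb <- nb + 1L
    }
    avg <- sums / nb
    bn_recalibrate(model, x_tr, bs)
    dev_mae <- dev_rmse <- NA_real_
    if (!is.null(x_dv)) {
      pd <- predict_scores(model, x_dv, bs)
      dev_mae <- bdi_mae(y_dv, pd)
      dev_rmse <- bdi_rmse(y_dv, pd)
      if (dev_mae < best$mae) {
        best$mae <- dev_mae
        best$epoch <- epoch
        best$state <- model_state(model)
      }
      sched$update(dev_mae)
    }
    history[[epoch]] <- tibble(
      epoch = epoch, l_mse = avg[["l_mse"]], l_att = avg[["l_att"]],
      l_sum = avg[["l_sum"]], dev_mae = dev_mae, dev_rmse = dev_rmse,
      lr = sched$lr)
    if (verbose)
      message(sprintf(
        "epoch %2d  L_sum %8.3f (mse %8.3f, att %6.3f)  dev MAE %s  lr %g",
        epoch, avg[["l_sum"]], avg[["l_mse"]], avg[["l_att"]],
        ifelse(is.na(dev_mae), "-", sprintf("%6.3f", dev_mae)), sched$lr))
  }
  if (!is.null(best$state)) set_model_state(model, best$state)
  structure(list(model = model, config = config,
                 history = dplyr::bind_rows(history),
                 best_epoch = if (best$epoch > 0) best$epoch else NA_integer_,
                 dev_mae = if (is.finite(best$mae)) best$mae else NA_real_),
            class = "hmhn_fit")
}

#' @export
print.hmhn_fit <- function(x, ...) {
  cat(sprintf(
    "<hmhn fit> %d epoch(s), best epoch %s (dev MAE %s)\n",
    nrow(x$history), format(x$best_epoch),
    ifelse(is.na(x$dev_mae), "-", sprintf("%.3f", x$dev_mae))))
  invisible(x)
}

#' Predict BDI-II scores
#'
#' @param object An `hmhn_fit`.
#' @param newdata A manifest tibble (with `abs_path` or `path`), a
#'   character vector of image paths, or an `(H, W, 3, N)` array already
#'   matching the model's image size.
#' @param base_dir Directory image paths are relative to.
#' @param ... Unused.
#' @return Tibble with `.pred` (clamped to \[0, 63\]) and `.pred_band`,
#'   preceded by `path` and `bdi2_score` columns when available.
#' @export
predict.hmhn_fit <- function(object, newdata, base_dir = ".", ...) {
  sz <- object$config$image_size
  info <- NULL
  if (is.array(newdata) && length(dim(newdata)) == 4) {
    x <- newdata
  } else {
    if (is.character(newdata)) newdata <- tibble(path = newdata)
    paths <- if ("abs_path" %in% names(newdata)) newdata$abs_path
             else file.path(base_dir, newdata$path)
    x <- load_image_batch(paths, sz)
    info <- tibble(path = newdata$path)
    if ("bdi2_score" %in% names(newdata))
      info$bdi2_score <- newdata$bdi2_score
  }
  raw <- predict_scores(object$model, x, object$config$batch_size)
  pred <- pmin(pmax(raw, 0), 63)
  out <- tibble(.pred = pred, .pred_band = severity_from_score(pred))
  if (!is.null(info)) out <- dplyr::bind_cols(info, out)
  out
}

#' Tidy the training history
#'
#' @param x An `hmhn_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @export
tidy.hmhn_fit <- function(x, ...) x$history

#' One-row fit summary
#'
#' @param x An `hmhn_fit`.
#' @param ... Unused.
#' @return Tibble with `epochs`, `best_epoch`, `dev_mae`, `final_l_sum`,
#'   `n_parameters`.
#' @export
glance.hmhn_fit <- function(x, ...) {
  tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
         dev_mae = x$dev_mae,
         final_l_sum = x$history$l_sum[nrow(x$history)],
         n_parameters = count_parameters(x$model))
}

#' Evaluate a fitted model on a manifest split
#'
#' @param fit An `hmhn_fit`.
#' @param manifest Manifest tibble or CSV path.
#' @param split Which split to score (default `"test"`).
#' @param base_dir Directory image paths are relative to.
#' @return As [evaluate_scores()]: a list with `metrics` and `confusion`.
#' @export
hmhn_evaluate <- function(fit, manifest, split = "test", base_dir = ".") {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  rows <- manifest[manifest$split == split, ]
  if (nrow(rows) == 0)
    abort(sprintf("manifest has no '%s' rows", split))
  pred <- predict.hmhn_fit(fit, rows, base_dir = base_dir)
  evaluate_scores(rows$bdi2_score, pred$.pred)
}
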