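# AdamW for the R-side layers and the plateau learning-rate schedule. The
# single-precision modules (backbone, feature fusion, spatial attention
# stacks) keep their own AdamW state in C++ and share the step counter and
# learning rate with this optimiser.

# Decoupled weight decay applies to convolution/linear weights only, not
# to biases or batch-norm scale/shift.
adamw_layer_step <- function(l, lr, beta1, beta2, eps, wd, t) {
  for (p in names(layer_params(l))) {
    g <- get(layer_grad_name[[p]], envir = l)
    mn <- paste0("m_", p); vn <- paste0("v_", p)
    if (is.null(l[[mn]])) {
      assign(mn, g * 0, envir = l)
      assign(vn, g * 0, envir = l)
    }
    m <- beta1 * l[[mn]] + (1 - beta1) * g
    v <- beta2 * l[[vn]] + (1 - beta2) * g^2
    assign(mn, m, envir = l)
    assign(vn, v, envir = l)
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    w <- get(p, envir = l)
    upd <- mh / (sqrt(vh) + eps)
    if (p == "w") upd <- upd + wd * w
    assign(p, w - lr * upd, envir = l)
  }
  invisible(l)
}

# One AdamW step over the whole model with step counter t.
optimizer_step <- function(model, lr, t, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8, wd = 0.01) {
  for (l in collect_layers(model))
    adamw_layer_step(l, lr, beta1, beta2, eps, wd, t)
  fb_step(model$backbone, lr, beta1, beta2, eps, wd, t)
  if (inherits(model$dff, "hmhn_fast_dff"))
    dff_step(model$dff, lr, beta1, beta2, eps, wd, t)
  if (!is.null(model$mab))
    for (hd in model$mab$heads)
      if (inherits(hd$spatial, "hmhn_fast_stack"))
        cs_step(hd$spatial, lr, beta1, beta2, eps, wd, t)
  invisible(model)
}

# Reduce-on-plateau schedule: multiply the learning rate by `factor` when
# the monitored value (dev MAE) has not improved for `patience` epochs.
plateau_scheduler <- function(lr, factor = 0.1, patience = 3L,
                              min_lr = 1e-6) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$best <- Inf; e$wait <- 0L
  e$update <- function(value) {
    if (is.finite(value) && value < e$best - 1e-12) {
      e$best <- value
      e$wait <- 0L
    } else {
      e$wait <- e$wait + 1L
      if (e$wait >= patience) {
        e$lr <- max(e$lr * factor, min_lr)
        e$wait <- 0L
      }
    }
    e$lr
  }
  e
}
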