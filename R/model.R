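# Full model: grid-wise attention -> deep feature fusion -> ResNet-18
# feature extractor -> parallel cross-attention heads -> attention fusion
# and BDI-II regression. Every stage can be toggled off, which reproduces
# the ablation variants (backbone only; + grid attention; + feature fusion;
# backbone + heads; everything).

#' Model and training configuration
#'
#' Collects every tunable of the network and its training loop. The
#' defaults are the reference configuration: a 3x3 grid, four separable
#' (3x3, 1x3, 3x1) cross-attention heads, AdamW with learning rate 0.001
#' decayed by 0.1 on a dev-MAE plateau, batch size 64 and dropout 0.2.
#'
#' @param grid_h,grid_w Grid rows/columns for the grid-wise attention stage.
#' @param k_e Channel expansion factor of the grid feature extractor.
#' @param ft_hidden Hidden width of the two feature-transformation nets.
#' @param image_size Input image side length (images are square).
#' @param channels Input channel count.
#' @param num_heads,kernel_config,reduce_channels,head_widths,channel_bottleneck
#'   Cross-attention head settings; see [head_config()].
#' @param dropout Dropout rate before the regression layer.
#' @param fusion `"mean"` (element-wise mean of head maps) or `"concat"`
#'   (channel concatenation followed by a 1x1 convolution).
#' @param use_gwa,use_dff,use_mab Stage toggles for ablations.
#' @param use_partition Include the partition loss in the objective.
#' @param loss_eps Variance floor of the partition loss.
#' @param lr,lr_decay_factor,plateau_patience,weight_decay,batch_size,epochs
#'   Optimiser settings (AdamW; the learning rate is multiplied by
#'   `lr_decay_factor` when the dev MAE has not improved for
#'   `plateau_patience` epochs).
#' @param pad_policy Border policy when the image size is not a grid
#'   multiple; see [grid_spec()].
#' @param seed Integer seed controlling initialisation and training.
#' @return A list of class `hmhn_config`.
#' @export
hmhn_config <- function(grid_h = 3L, grid_w = 3L, k_e = 4L,
                        ft_hidden = 16L, image_size = 224L, channels = 3L,
                        num_heads = 4L, kernel_config = "k313",
                        reduce_channels = 192L, head_widths = c(416L, 960L),
                        channel_bottleneck = 112L,
                        dropout = 0.2, fusion = c("mean", "concat"),
                        use_gwa = TRUE, use_dff = TRUE, use_mab = TRUE,
                        use_partition = TRUE, loss_eps = 1e-6,
                        lr = 0.001, lr_decay_factor = 0.1,
                        plateau_patience = 3L, weight_decay = 0.01,
                        batch_size = 64L, epochs = 10L,
                        pad_policy = "reflect", seed = 42L) {
  fusion <- match.arg(fusion)
  if (lr <= 0) abort("lr must be positive")
  if (batch_size < 1) abort("batch_size must be >= 1")
  cfg <- list(grid_h = as.integer(grid_h), grid_w = as.integer(grid_w),
              k_e = as.integer(k_e), ft_hidden = as.integer(ft_hidden),
              image_size = as.integer(image_size),
              channels = as.integer(channels),
              num_heads = as.integer(num_heads),
              kernel_config = kernel_config,
              reduce_channels = as.integer(reduce_channels),
              head_widths = as.integer(head_widths),
              channel_bottleneck = as.integer(channel_bottleneck),
              dropout = dropout, fusion = fusion,
              use_gwa = isTRUE(use_gwa), use_dff = isTRUE(use_dff),
              use_mab = isTRUE(use_mab),
              use_partition = isTRUE(use_partition), loss_eps = loss_eps,
              lr = lr, lr_decay_factor = lr_decay_factor,
              plateau_patience = as.integer(plateau_patience),
              weight_decay = weight_decay,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              pad_policy = pad_policy, seed = as.integer(seed))
  structure(cfg, class = "hmhn_config")
}

#' Construct the network
#'
#' Builds all enabled stages with freshly initialised parameters (He
#' initialisation for convolution and linear weights; batch-norm scale 1,
#' shift 0). Construction is seeded from `config$seed` so two calls with
#' the same configuration yield identical parameters.
#'
#' @param config An [hmhn_config()].
#' @return An object of class `hmhn_model`.
#' @examples
#' m <- hmhn_model(hmhn_config(seed = 1))
#' count_parameters(m)
#' @export
hmhn_model <- function(config = hmhn_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  spec <- grid_spec(config$grid_h, config$grid_w, config$image_size,
                    config$image_size, config$channels,
                    pad_policy = config$pad_policy)
  hcfg <- head_config(config$num_heads, config$kernel_config,
                      config$reduce_channels, config$head_widths,
                      config$channel_bottleneck)
  cb <- 512L
  m <- list(config = config, spec = spec,
            gwa = if (config$use_gwa) gwa_module(spec, config$k_e),
            dff = if (config$use_dff) fast_dff(config$channels,
                                               config$ft_hidden),
            backbone = fast_backbone(config$channels),
            mab = if (config$use_mab) mab_module(cb, hcfg),
            concat_fuse = if (config$use_mab && config$fusion == "concat")
              nn_conv2d(cb * config$num_heads, cb, 1, 1),
            afb = afb_module(cb, config$dropout),
            cache = new.env(parent = emptyenv()))
  structure(m, class = "hmhn_model")
}

#' @export
print.hmhn_model <- function(x, ...) {
  cfg <- x$config
  stages <- c(if (cfg$use_gwa) "GWA", if (cfg$use_dff) "DFF", "ResNet-18",
              if (cfg$use_mab) sprintf("MAB[%d heads, %s]", cfg$num_heads,
                                       cfg$kernel_config), "AFB")
  cat(sprintf("<hmhn model> %s | %s grid | %s parameters\n",
              paste(stages, collapse = " -> "),
              paste0(cfg$grid_h, "x", cfg$grid_w),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

collect_layers <- function(model) {
  out <- list()
  if (!is.null(model$gwa)) out <- c(out, seq_layers(model$gwa$lgfe))
  if (!is.null(model$dff)) out <- c(out, dff_layers(model$dff))
  out <- c(out, backbone_layers(model$backbone))
  if (!is.null(model$mab)) out <- c(out, mab_layers(model$mab))
  if (!is.null(model$concat_fuse)) out <- c(out, list(model$concat_fuse))
  c(out, afb_layers(model$afb))
}

zero_grads <- function(model) {
  for (l in collect_layers(model)) zero_grad(l)
  if (inherits(model$backbone, "hmhn_fast_backbone"))
    cpp_bb_zero_grads(model$backbone$ptr)
  if (inherits(model$dff, "hmhn_fast_dff"))
    cpp_dff_zero_grads(model$dff$ptr)
  if (!is.null(model$mab))
    for (hd in model$mab$heads)
      if (inherits(hd$spatial, "hmhn_fast_stack"))
        cpp_cs_zero_grads(hd$spatial$ptr)
  invisible(model)
}

# Forward pass over a batch x (H, W, C, N).
# Returns pred (N-vector), the per-head channel-attended maps and gates.
model_forward <- function(model, x, train = TRUE) {
  cfg <- model$config
  cc <- model$cache
  gt <- if (cfg$use_gwa) gwa_forward(model$gwa, x, train)
  fin <- if (cfg$use_dff) dff_forward(model$dff, x, gt %||% x, train)
         else gt %||% x
  feat <- backbone_forward(model$backbone, fin, train)
  if (cfg$use_mab) {
    mo <- mab_forward(model$mab, feat, train)
    fused <- if (cfg$fusion == "concat") {
      cc$cmaps_dim <- dim(mo$c_maps[[1]])
      layer_forward(model$concat_fuse, abind4(mo$c_maps), train)
    } else fuse_heads(mo$c_maps)
  } else {
    mo <- NULL
    fused <- feat
  }
  pred <- afb_forward(model$afb, fused, train)
  list(pred = pred, c_maps = mo$c_maps,
       spatial_gates = mo$spatial_gates, channel_gates = mo$channel_gates)
}

# concatenate a list of (H, W, C, N) arrays along the channel axis
abind4 <- function(lst) {
  d <- dim(lst[[1]])
  k <- length(lst)
  out <- array(0, c(d[1], d[2], d[3] * k, d[4]))
  for (i in seq_len(k))
    out[, , (i - 1L) * d[3] + seq_len(d[3]), ] <- lst[[i]]
  out
}

# Backward pass. dpred: gradient on predictions (length N);
# datt: optional list of k (H, W, C, N) gradients on the head maps coming
# from the partition loss.
model_backward <- function(model, dpred, datt = NULL) {
  cfg <- model$config
  dfused <- afb_backward(model$afb, dpred)
  if (cfg$use_mab) {
    k <- cfg$num_heads
    if (cfg$fusion == "concat") {
      dcat <- layer_backward(model$concat_fuse, dfused)
      d <- model$cache$cmaps_dim
      dc <- lapply(seq_len(k), function(i)
        dcat[, , (i - 1L) * d[3] + seq_len(d[3]), , drop = FALSE])
    } else {
      dc <- rep(list(dfused / k), k)
    }
    if (!is.null(datt))
      dc <- Map(function(a, b) a + b, dc, datt)
    dfeat <- mab_backward(model$mab, dc)
  } else {
    dfeat <- dfused
  }
  need_front <- cfg$use_gwa || cfg$use_dff
  dfin <- backbone_backward(model$backbone, dfeat, need_dx = need_front)
  if (!need_front) return(invisible(model))
  dgt <- if (cfg$use_dff) dff_backward(model$dff, dfin) else dfin
  if (cfg$use_gwa) gwa_backward(model$gwa, dgt)
  invisible(model)
}

# Deterministic eval-mode scores for a batch.
model_predict <- function(model, x) {
  model_forward(model, x, train = FALSE)$pred
}
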