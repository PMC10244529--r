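# Multi-head cross attention block (MAB): k independent heads applied in
# parallel to the backbone feature map. Each head is a spatial attention
# unit (a 1x1 channel-reducing convolution followed by three separable
# convolutions and a sigmoid, producing a one-channel gate over space)
# chained with a channel attention unit (a two-linear-layer bottleneck over
# globally pooled channels -- a mini autoencoder -- with a sigmoid gate).
# Separable 1xN / Nx1 kernels keep the parameter budget low relative to
# full NxN convolutions.

# kernel shapes of the three (or two) convolutions after the 1x1 reduction
kernel_configs <- list(
  standard = list(c(3L, 3L), c(3L, 3L), c(3L, 3L)),
  k7       = list(c(1L, 7L), c(7L, 7L), c(7L, 1L)),
  k5       = list(c(1L, 5L), c(5L, 5L), c(5L, 1L)),
  k31      = list(c(3L, 1L), c(1L, 3L)),
  k313     = list(c(3L, 3L), c(1L, 3L), c(3L, 1L)))

#' Configuration of the cross-attention heads
#'
#' @param num_heads Number of parallel cross-attention heads (default 4).
#' @param kernel_config One of `"k313"` (separable 3x3, 1x3, 3x1; default),
#'   `"standard"` (three full 3x3), `"k7"`, `"k5"`, or `"k31"`.
#' @param reduce_channels Output width of the 1x1 reducing convolution.
#' @param head_widths Widths of the intermediate convolutions in the spatial
#'   unit; the final convolution always emits a single gate channel.
#' @param channel_bottleneck Hidden width of the channel-attention
#'   autoencoder.
#' @return A list of class `hmhn_head_config`.
#' @export
head_config <- function(num_heads = 4L,
                        kernel_config = c("k313", "standard", "k7", "k5",
                                          "k31"),
                        reduce_channels = 192L,
                        head_widths = c(416L, 960L),
                        channel_bottleneck = 112L) {
  kernel_config <- match.arg(kernel_config)
  if (num_heads < 1) abort("num_heads must be >= 1")
  structure(list(num_heads = as.integer(num_heads),
                 kernel_config = kernel_config,
                 reduce_channels = as.integer(reduce_channels),
                 head_widths = as.integer(head_widths),
                 channel_bottleneck = as.integer(channel_bottleneck)),
            class = "hmhn_head_config")
}

same_pad <- function(k) as.integer((k - 1L) %/% 2L)

make_spatial_unit <- function(cin, cfg) {
  kernels <- kernel_configs[[cfg$kernel_config]]
  widths <- c(cfg$reduce_channels, cfg$head_widths)
  widths <- widths[seq_len(length(kernels))]       # k31 uses one fewer width
  chans <- c(cin, widths, 1L)
  layers <- list(nn_conv2d(cin, chans[2], 1, 1))
  for (i in seq_along(kernels)) {
    k <- kernels[[i]]
    layers <- c(layers, list(
      nn_conv2d(chans[i + 1], chans[i + 2], k[1], k[2],
                pad = same_pad(k))))
  }
  layers <- c(layers, list(nn_act("sigmoid")))
  do.call(nn_sequential, layers)
}

make_channel_unit <- function(cin, cfg) {
  nn_sequential(nn_linear(cin, cfg$channel_bottleneck),
                nn_act("leaky_relu"),
                nn_linear(cfg$channel_bottleneck, cin),
                nn_act("sigmoid"))
}

cross_head <- function(cin, cfg, fast = TRUE) {
  structure(list(spatial = if (fast) fast_spatial_unit(cin, cfg)
                           else make_spatial_unit(cin, cfg),
                 channel = make_channel_unit(cin, cfg),
                 cache = new.env(parent = emptyenv())),
            class = "hmhn_cross_head")
}

spatial_forward <- function(sp, x, train = TRUE) {
  if (inherits(sp, "hmhn_fast_stack"))
    return(cpp_cs_forward(sp$ptr, x, as.integer(dim(x)), train))
  seq_forward(sp, x, train)
}

spatial_backward <- function(sp, dy, need_dx = TRUE) {
  if (inherits(sp, "hmhn_fast_stack"))
    return(cpp_cs_backward(sp$ptr, dy, need_dx))
  seq_backward(sp, dy, need_dx)
}

# broadcast helpers for (H, W, C, N) arrays
expand_spatial_gate <- function(gate, C) {
  gate[, , rep(1L, C), , drop = FALSE]
}

expand_channel_gate <- function(gate, xdim) {
  # gate is N x C
  v <- as.vector(t(gate))
  array(rep(v, each = xdim[1] * xdim[2]), dim = xdim)
}

head_forward <- function(hd, x, train = TRUE) {
  d <- dim(x)
  gs <- spatial_forward(hd$spatial, x, train)      # (H, W, 1, N) in (0,1)
  gse <- expand_spatial_gate(gs, d[3])
  s <- x * gse
  v <- gap_forward(s)                              # N x C
  gc <- seq_forward(hd$channel, v, train)          # N x C in (0,1)
  gce <- expand_channel_gate(gc, d)
  cmap <- s * gce
  cc <- hd$cache
  cc$x <- x; cc$gse <- gse; cc$s <- s; cc$gc <- gc; cc$gce <- gce
  list(s = s, c = cmap, spatial_gate = gs, channel_gate = gc)
}

head_backward <- function(hd, dc) {
  cc <- hd$cache
  d <- dim(cc$x)
  hw <- d[1] * d[2]
  # channel gate path
  ds <- dc * cc$gce
  dgc <- t(matrix(colSums(matrix(dc * cc$s, nrow = hw)), nrow = d[3]))
  dv <- seq_backward(hd$channel, dgc)
  ds <- ds + gap_backward(dv, d)
  # spatial gate path
  dx <- ds * cc$gse
  m <- aperm(ds * cc$x, c(1, 2, 4, 3))
  dgs <- array(rowSums(matrix(m, nrow = hw * d[4])), dim = c(d[1], d[2], 1, d[4]))
  dx <- dx + spatial_backward(hd$spatial, dgs)
  cc$x <- NULL; cc$gse <- NULL; cc$s <- NULL; cc$gc <- NULL; cc$gce <- NULL
  dx
}

head_layers <- function(hd) {
  sp <- if (inherits(hd$spatial, "hmhn_fast_stack")) list()
        else seq_layers(hd$spatial)
  c(sp, seq_layers(hd$channel))
}

head_n_params <- function(hd) {
  sp <- if (inherits(hd$spatial, "hmhn_fast_stack")) cs_n_params(hd$spatial)
        else sum(vapply(seq_layers(hd$spatial), n_params_layer, 0))
  sp + sum(vapply(seq_layers(hd$channel), n_params_layer, 0))
}

mab_module <- function(cin, cfg) {
  structure(list(heads = lapply(seq_len(cfg$num_heads),
                                function(i) cross_head(cin, cfg)),
                 cfg = cfg),
            class = "hmhn_mab")
}

# Returns a list with per-head channel-attended maps and the gates.
mab_forward <- function(mod, x, train = TRUE) {
  outs <- lapply(mod$heads, head_forward, x = x, train = train)
  list(c_maps = lapply(outs, `[[`, "c"),
       spatial_gates = lapply(outs, `[[`, "spatial_gate"),
       channel_gates = lapply(outs, `[[`, "channel_gate"))
}

mab_backward <- function(mod, dc_list) {
  dx <- NULL
  for (i in seq_along(mod$heads)) {
    dxi <- head_backward(mod$heads[[i]], dc_list[[i]])
    dx <- if (is.null(dx)) dxi else dx + dxi
  }
  dx
}

mab_layers <- function(mod) {
  unlist(lapply(mod$heads, head_layers), recursive = FALSE)
}

#' Count trainable parameters
#'
#' Sums the element counts of every trainable tensor (convolution and
#' linear weights and biases, batch-norm scales and shifts) in a model or
#' module. Batch-norm running statistics are buffers, not parameters, and
#' are excluded.
#'
#' @param model An `hmhn_model` (or any object with collectable layers).
#' @return Integer parameter count.
#' @examples
#' count_parameters(hmhn_model(hmhn_config(seed = 1)))
#' @export
count_parameters <- function(model) {
  n <- sum(vapply(collect_layers(model), n_params_layer, 0))
  if (inherits(model$backbone, "hmhn_fast_backbone"))
    n <- n + backbone_n_params(model$backbone)
  if (inherits(model$dff, "hmhn_fast_dff"))
    n <- n + dff_n_params(model$dff)
  if (!is.null(model$mab))
    for (hd in model$mab$heads)
      if (inherits(hd$spatial, "hmhn_fast_stack"))
        n <- n + cs_n_params(hd$spatial)
  n
}
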