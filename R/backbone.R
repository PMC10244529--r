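# ResNet-18 feature extractor without its classification head: the stem and
# the four residual stages are kept; average pooling, flattening and the
# fully connected layer are removed, so a 3x224x224 input yields a
# 512-channel 7x7 feature map. Trained from scratch; no pretrained weights.

basic_block <- function(cin, cout, stride = 1L) {
  b <- list(
    conv1 = nn_conv2d(cin, cout, 3, 3, stride = stride, pad = c(1L, 1L),
                      bias = FALSE),
    bn1   = nn_batchnorm(cout),
    act1  = nn_act("relu"),
    conv2 = nn_conv2d(cout, cout, 3, 3, stride = 1L, pad = c(1L, 1L),
                      bias = FALSE),
    bn2   = nn_batchnorm(cout),
    act2  = nn_act("relu"))
  if (stride != 1L || cin != cout) {
    b$ds_conv <- nn_conv2d(cin, cout, 1, 1, stride = stride, bias = FALSE)
    b$ds_bn <- nn_batchnorm(cout)
  }
  structure(b, class = "hmhn_basic_block")
}

block_forward <- function(b, x, train = TRUE) {
  out <- layer_forward(b$conv1, x, train)
  out <- layer_forward(b$bn1, out, train)
  out <- layer_forward(b$act1, out, train)
  out <- layer_forward(b$conv2, out, train)
  out <- layer_forward(b$bn2, out, train)
  sc <- if (!is.null(b$ds_conv)) {
    layer_forward(b$ds_bn, layer_forward(b$ds_conv, x, train), train)
  } else x
  layer_forward(b$act2, out + sc, train)
}

block_backward <- function(b, dy, need_dx = TRUE) {
  d <- layer_backward(b$act2, dy)
  dmain <- layer_backward(b$bn2, d)
  dmain <- layer_backward(b$conv2, dmain)
  dmain <- layer_backward(b$act1, dmain)
  dmain <- layer_backward(b$bn1, dmain)
  dmain <- layer_backward(b$conv1, dmain, need_dx = need_dx)
  if (!is.null(b$ds_conv)) {
    dsc <- layer_backward(b$ds_bn, d)
    dsc <- layer_backward(b$ds_conv, dsc, need_dx = need_dx)
  } else dsc <- d
  if (!need_dx) return(NULL)
  dmain + dsc
}

block_layers <- function(b) {
  out <- list(b$conv1, b$bn1, b$conv2, b$bn2)
  if (!is.null(b$ds_conv)) out <- c(out, list(b$ds_conv, b$ds_bn))
  out
}

resnet18_backbone <- function(cin = 3L) {
  structure(list(
    conv1 = nn_conv2d(cin, 64, 7, 7, stride = 2L, pad = c(3L, 3L),
                      bias = FALSE),
    bn1   = nn_batchnorm(64),
    act1  = nn_act("relu"),
    pool  = nn_maxpool(3, 3, stride = 2L, pad = c(1L, 1L)),
    blocks = list(
      basic_block(64, 64), basic_block(64, 64),
      basic_block(64, 128, stride = 2L), basic_block(128, 128),
      basic_block(128, 256, stride = 2L), basic_block(256, 256),
      basic_block(256, 512, stride = 2L), basic_block(512, 512))),
    class = "hmhn_resnet18")
}

backbone_forward <- function(bb, x, train = TRUE) {
  if (length(dim(x)) != 4) abort("backbone expects a (H, W, C, N) array")
  if (inherits(bb, "hmhn_fast_backbone"))
    return(cpp_bb_forward(bb$ptr, x, as.integer(dim(x)), train))
  out <- layer_forward(bb$conv1, x, train)
  out <- layer_forward(bb$bn1, out, train)
  out <- layer_forward(bb$act1, out, train)
  out <- layer_forward(bb$pool, out, train)
  for (b in bb$blocks) out <- block_forward(b, out, train)
  out
}

backbone_backward <- function(bb, dy, need_dx = TRUE) {
  if (inherits(bb, "hmhn_fast_backbone"))
    return(cpp_bb_backward(bb$ptr, dy, need_dx))
  for (b in rev(bb$blocks)) dy <- block_backward(b, dy)
  dy <- layer_backward(bb$pool, dy)
  dy <- layer_backward(bb$act1, dy)
  dy <- layer_backward(bb$bn1, dy)
  layer_backward(bb$conv1, dy, need_dx = need_dx)
}

backbone_layers <- function(bb) {
  if (inherits(bb, "hmhn_fast_backbone")) return(list())
  c(list(bb$conv1, bb$bn1),
    unlist(lapply(bb$blocks, block_layers), recursive = FALSE))
}

backbone_n_params <- function(bb) {
  if (inherits(bb, "hmhn_fast_backbone"))
    return(cpp_bb_count_params(bb$ptr))
  sum(vapply(backbone_layers(bb), n_params_layer, 0))
}
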