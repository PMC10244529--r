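# Minimal trainable layer primitives on dense arrays.
#
# Tensors are base-R double arrays in (H, W, C, N) layout; the convolution
# and pooling kernels live in src/conv_ops.cpp and compute in single
# precision. Each layer is an environment so that gradients accumulate by
# reference during backpropagation; `forward()` caches whatever its
# `backward()` needs, which keeps one batch of activations alive at a time.

new_layer <- function(type, ...) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = l)
  class(l) <- c(paste0("hmhn_", type), "hmhn_layer")
  l
}

#' @noRd
he_init <- function(dim, fan_in) {
  array(stats::rnorm(prod(dim), sd = sqrt(2 / fan_in)), dim = dim)
}

nn_conv2d <- function(cin, cout, kh, kw, stride = 1L, pad = c(0L, 0L),
                      bias = TRUE) {
  stopifnot(cin >= 1, cout >= 1, kh >= 1, kw >= 1, stride >= 1)
  l <- new_layer("conv2d",
                 w  = he_init(c(kh, kw, cin, cout), fan_in = kh * kw * cin),
                 b  = if (bias) numeric(cout) else NULL,
                 stride = as.integer(stride), pad = as.integer(pad))
  zero_grad(l)
  l
}

nn_batchnorm <- function(c, eps = 1e-5, momentum = 0.1) {
  l <- new_layer("batchnorm",
                 gamma = rep(1, c), beta = numeric(c),
                 run_mean = numeric(c), run_var = rep(1, c),
                 eps = eps, momentum = momentum)
  zero_grad(l)
  l
}

nn_linear <- function(fin, fout) {
  l <- new_layer("linear",
                 w = matrix(stats::rnorm(fin * fout, sd = sqrt(2 / fin)),
                            fin, fout),
                 b = numeric(fout))
  zero_grad(l)
  l
}

# act one of "relu", "leaky_relu" (slope 0.01), "sigmoid"
nn_act <- function(act) new_layer("act", act = act)

nn_maxpool <- function(kh, kw, stride, pad = c(0L, 0L)) {
  new_layer("maxpool", kh = as.integer(kh), kw = as.integer(kw),
            stride = as.integer(stride), pad = as.integer(pad))
}

nn_dropout <- function(rate) new_layer("dropout", rate = rate)

zero_grad <- function(l) {
  if (!is.null(l$w)) l$gw <- array(0, dim = dim(l$w) %||% length(l$w))
  if (!is.null(l$b)) l$gb <- numeric(length(l$b))
  if (!is.null(l$gamma)) { l$ggamma <- numeric(length(l$gamma))
                           l$gbeta  <- numeric(length(l$beta)) }
  invisible(l)
}

layer_params <- function(l) {
  switch(l$type,
    conv2d   = if (is.null(l$b)) list(w = "w") else list(w = "w", b = "b"),
    linear   = list(w = "w", b = "b"),
    batchnorm = list(gamma = "gamma", beta = "beta"),
    list())
}

layer_grad_name <- c(w = "gw", b = "gb", gamma = "ggamma", beta = "gbeta")

n_params_layer <- function(l) {
  sum(vapply(layer_params(l), function(f) length(get(f, envir = l)), 0))
}

# ---- forward / backward dispatch -------------------------------------------

layer_forward <- function(l, x, train = TRUE) {
  switch(l$type,
    conv2d    = conv_forward(l, x),
    batchnorm = bn_forward(l, x, train),
    act       = act_forward(l, x),
    maxpool   = pool_forward(l, x),
    linear    = linear_forward(l, x),
    dropout   = dropout_forward(l, x, train),
    abort(paste0("unknown layer type: ", l$type)))
}

layer_backward <- function(l, dy, need_dx = TRUE) {
  switch(l$type,
    conv2d    = conv_backward(l, dy, need_dx),
    batchnorm = bn_backward(l, dy),
    act       = act_backward(l, dy),
    maxpool   = pool_backward(l, dy),
    linear    = linear_backward(l, dy),
    dropout   = dropout_backward(l, dy),
    abort(paste0("unknown layer type: ", l$type)))
}

# ---- conv -------------------------------------------------------------------

conv_forward <- function(l, x) {
  d <- dim(x)
  if (length(d) != 4) abort("conv2d expects a (H, W, C, N) array")
  l$x <- x
  cpp_conv2d_forward(x, as.integer(d), l$w, as.integer(dim(l$w)),
                     if (is.null(l$b)) numeric(0) else l$b,
                     l$stride, l$stride, l$pad[1], l$pad[2])
}

conv_backward <- function(l, dy, need_dx = TRUE) {
  g <- cpp_conv2d_backward(l$x, as.integer(dim(l$x)), l$w,
                           as.integer(dim(l$w)), dy,
                           l$stride, l$stride, l$pad[1], l$pad[2],
                           !is.null(l$b), need_dx)
  l$gw <- l$gw + g$dw
  if (!is.null(l$b)) l$gb <- l$gb + g$db
  l$x <- NULL
  g$dx
}

# ---- batchnorm --------------------------------------------------------------

bn_forward <- function(l, x, train = TRUE) {
  d <- dim(x)
  if (train) {
    out <- cpp_bn_forward_train(x, as.integer(d), l$gamma, l$beta, l$eps)
    m <- d[1] * d[2] * d[4]
    l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * out$mu
    vu <- if (m > 1) out$var * m / (m - 1) else out$var
    l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * vu
    l$x <- x
    l$mu <- out$mu
    l$invstd <- out$invstd
    out$y
  } else {
    scale <- l$gamma / sqrt(l$run_var + l$eps)
    shift <- l$beta - l$run_mean * scale
    cpp_bn_forward_eval(x, as.integer(d), scale, shift)
  }
}

bn_backward <- function(l, dy) {
  g <- cpp_bn_backward(l$x, as.integer(dim(l$x)), l$mu, l$invstd,
                       l$gamma, dy)
  l$ggamma <- l$ggamma + g$dgamma
  l$gbeta <- l$gbeta + g$dbeta
  l$x <- NULL
  g$dx
}

# ---- activations ------------------------------------------------------------

act_forward <- function(l, x) {
  switch(l$act,
    relu = { l$x <- x; cpp_slope_relu_forward(x, 0) },
    leaky_relu = { l$x <- x; cpp_slope_relu_forward(x, 0.01) },
    sigmoid = { y <- 1 / (1 + exp(-x)); l$y <- y; y },
    abort(paste0("unknown activation: ", l$act)))
}

act_backward <- function(l, dy) {
  out <- switch(l$act,
    relu = cpp_slope_relu_backward(l$x, dy, 0),
    leaky_relu = cpp_slope_relu_backward(l$x, dy, 0.01),
    sigmoid = dy * l$y * (1 - l$y))
  l$x <- NULL; l$y <- NULL
  out
}

# ---- pooling ----------------------------------------------------------------

pool_forward <- function(l, x) {
  d <- dim(x)
  out <- cpp_maxpool_forward(x, as.integer(d), l$kh, l$kw,
                             l$stride, l$stride, l$pad[1], l$pad[2])
  l$idx <- out$idx
  l$xdim <- d
  out$y
}

pool_backward <- function(l, dy) {
  dx <- cpp_maxpool_backward(dy, l$idx, as.integer(l$xdim))
  l$idx <- NULL
  dx
}

# global average pool: (H, W, C, N) -> (N, C) matrix
gap_forward <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  cs <- colSums(matrix(x, nrow = hw)) / hw
  t(matrix(cs, nrow = d[3]))
}

gap_backward <- function(dy, xdim) {
  hw <- xdim[1] * xdim[2]
  v <- as.vector(t(dy)) / hw           # ordered (C fastest, then N)
  array(rep(v, each = hw), dim = xdim)
}

# ---- linear -----------------------------------------------------------------

linear_forward <- function(l, x) {
  l$x <- x
  sweep(x %*% l$w, 2, l$b, "+")
}

linear_backward <- function(l, dy, need_dx = TRUE) {
  l$gw <- l$gw + crossprod(l$x, dy)
  l$gb <- l$gb + colSums(dy)
  dx <- dy %*% t(l$w)
  l$x <- NULL
  dx
}

# ---- dropout ----------------------------------------------------------------

dropout_forward <- function(l, x, train = TRUE) {
  if (!train || l$rate <= 0) { l$mask <- NULL; return(x) }
  keep <- 1 - l$rate
  l$mask <- (stats::runif(length(x)) < keep) / keep
  y <- x * l$mask
  if (!is.null(dim(x))) dim(y) <- dim(x)
  y
}

dropout_backward <- function(l, dy) {
  if (is.null(l$mask)) return(dy)
  dx <- dy * l$mask
  if (!is.null(dim(dy))) dim(dx) <- dim(dy)
  l$mask <- NULL
  dx
}

# ---- sequential container ---------------------------------------------------

nn_sequential <- function(...) {
  layers <- list(...)
  structure(list(layers = layers), class = "hmhn_sequential")
}

seq_forward <- function(s, x, train = TRUE) {
  for (l in s$layers) x <- layer_forward(l, x, train)
  x
}

seq_backward <- function(s, dy, need_dx = TRUE) {
  n <- length(s$layers)
  for (i in rev(seq_len(n))) {
    dy <- layer_backward(s$layers[[i]], dy,
                         need_dx = need_dx || i > 1)
  }
  dy
}

seq_layers <- function(s) s$layers
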