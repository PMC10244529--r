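# Grid-wise attention (GWA).
#
# The image is split into an h x w lattice of grids, each grid is passed
# through a shared local grid feature extraction network (LGFE, a 1x1-conv
# bottleneck), grids are scored channel-wise with scaled dot-product
# attention over their rows, the attention matrix is squeezed to one scalar
# per (grid, channel) and broadcast back, and the resulting weight map
# multiplies the original image. Image sizes that are not multiples of the
# grid count are padded first (reflect by default) and the weight map is
# cropped back after reassembly.

#' Grid specification for grid-wise attention
#'
#' Describes how an `H x W x C` image is partitioned into an `h x w` lattice
#' of equally sized grids. When `H` (or `W`) is not a multiple of `h` (or
#' `w`) the image is padded on the bottom/right edge to the next multiple,
#' either by mirroring interior rows (`"reflect"`, the default) or with
#' zeros (`"zero"`).
#'
#' @param h,w Number of grid rows and columns (integers >= 1).
#' @param H,W,C Image height, width and channel count.
#' @param pad_policy `"reflect"` or `"zero"`.
#' @return An object of class `hmhn_grid_spec` with the padded dimensions
#'   (`H_pad`, `W_pad`) and the per-grid patch size (`ph`, `pw`).
#' @examples
#' grid_spec(3, 3, 224, 224)
#' @export
grid_spec <- function(h, w, H = 224L, W = 224L, C = 3L,
                      pad_policy = c("reflect", "zero")) {
  pad_policy <- match.arg(pad_policy)
  h <- as.integer(h); w <- as.integer(w)
  if (h < 1 || w < 1) abort("grid counts h and w must be >= 1")
  if (h > H || w > W) abort("grid counts cannot exceed the image size")
  H_pad <- as.integer(ceiling(H / h) * h)
  W_pad <- as.integer(ceiling(W / w) * w)
  structure(list(h = h, w = w, H = as.integer(H), W = as.integer(W),
                 C = as.integer(C), H_pad = H_pad, W_pad = W_pad,
                 ph = H_pad %/% h, pw = W_pad %/% w,
                 pad_policy = pad_policy),
            class = "hmhn_grid_spec")
}

#' @export
print.hmhn_grid_spec <- function(x, ...) {
  cat(sprintf("<grid spec> %dx%d grids over %dx%dx%d image (padded %dx%d, patch %dx%d, %s)\n",
              x$h, x$w, x$H, x$W, x$C, x$H_pad, x$W_pad, x$ph, x$pw,
              x$pad_policy))
  invisible(x)
}

# Pad an (H, W, C[, N]) array on the bottom/right edge to (H_pad, W_pad).
# Reflection mirrors interior rows (the edge row itself is not repeated).
pad_image <- function(x, spec) {
  d <- dim(x)
  dh <- spec$H_pad - d[1]; dw <- spec$W_pad - d[2]
  if (dh == 0 && dw == 0) return(x)
  idx_h <- c(seq_len(d[1]), if (dh > 0) d[1] - seq_len(dh))
  idx_w <- c(seq_len(d[2]), if (dw > 0) d[2] - seq_len(dw))
  if (spec$pad_policy == "zero") {
    out_dim <- d; out_dim[1] <- spec$H_pad; out_dim[2] <- spec$W_pad
    out <- array(0, out_dim)
    if (length(d) == 3) out[seq_len(d[1]), seq_len(d[2]), ] <- x
    else out[seq_len(d[1]), seq_len(d[2]), , ] <- x
    return(out)
  }
  if (any(idx_h < 1) || any(idx_w < 1))
    abort("image too small for reflect padding")
  if (length(d) == 3) x[idx_h, idx_w, , drop = FALSE]
  else x[idx_h, idx_w, , , drop = FALSE]
}

#' Partition an image into grids
#'
#' Splits an `H x W x C` image into the `h * w` grids of its grid
#' specification, padding first when needed. Grids are returned in row-major
#' order (left to right, then top to bottom) together with their origin
#' indices in the padded image.
#'
#' @param image Numeric array `H x W x C`, values typically in `[0, 1]`.
#' @param spec A [grid_spec()].
#' @return A list of class `hmhn_grid_set` with elements `grids` (array
#'   `ph x pw x C x (h*w)`), `origins` (a tibble with the grid row/column and
#'   the top-left pixel of each grid in the padded image) and `spec`.
#' @examples
#' img <- array(runif(6 * 6 * 3), c(6, 6, 3))
#' gs <- partition_grid(img, grid_spec(2, 2, 6, 6))
#' dim(gs$grids)
#' @export
partition_grid <- function(image, spec) {
  d <- dim(image)
  if (length(d) != 3) abort("partition_grid expects a 3-D (H, W, C) array")
  if (d[1] != spec$H || d[2] != spec$W || d[3] != spec$C)
    abort(sprintf("image is %dx%dx%d but spec expects %dx%dx%d",
                  d[1], d[2], d[3], spec$H, spec$W, spec$C))
  xp <- pad_image(image, spec)
  h <- spec$h; w <- spec$w; ph <- spec$ph; pw <- spec$pw
  grids <- array(0, c(ph, pw, spec$C, h * w))
  origins <- vector("list", h * w)
  g <- 0L
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      g <- g + 1L
      h0 <- (i - 1L) * ph; w0 <- (j - 1L) * pw
      grids[, , , g] <- xp[h0 + seq_len(ph), w0 + seq_len(pw), , drop = FALSE]
      origins[[g]] <- tibble(grid = g, row = i, col = j,
                             h0 = h0 + 1L, w0 = w0 + 1L)
    }
  }
  structure(list(grids = grids, origins = dplyr::bind_rows(origins),
                 spec = spec),
            class = "hmhn_grid_set")
}

#' Reassemble grids into the padded image
#'
#' The inverse of [partition_grid()]: places the `h * w` grids back at their
#' origins, producing the padded `H_pad x W_pad x C` array. Combined with
#' cropping this inverts the partition exactly.
#'
#' @param grids Either an `hmhn_grid_set` or a `ph x pw x C x (h*w)` array.
#' @param spec A [grid_spec()]; taken from the grid set when omitted.
#' @param crop If `TRUE`, crop the reassembled array back to `H x W`.
#' @return Numeric array `H_pad x W_pad x C` (or `H x W x C` when cropped).
#' @export
ungrid <- function(grids, spec = NULL, crop = FALSE) {
  if (inherits(grids, "hmhn_grid_set")) {
    spec <- spec %||% grids$spec
    grids <- grids$grids
  }
  if (is.null(spec)) abort("ungrid needs a grid spec")
  d <- dim(grids)
  if (length(d) != 4 || d[4] != spec$h * spec$w)
    abort(sprintf("expected %d grids, got %s", spec$h * spec$w,
                  paste(d, collapse = "x")))
  out <- array(0, c(spec$H_pad, spec$W_pad, spec$C))
  g <- 0L
  for (i in seq_len(spec$h)) {
    for (j in seq_len(spec$w)) {
      g <- g + 1L
      h0 <- (i - 1L) * spec$ph; w0 <- (j - 1L) * spec$pw
      out[h0 + seq_len(spec$ph), w0 + seq_len(spec$pw), ] <- grids[, , , g]
    }
  }
  if (crop) out[seq_len(spec$H), seq_len(spec$W), , drop = FALSE] else out
}

# ---- attention over grid features ------------------------------------------

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

#' Scaled dot-product attention within each grid
#'
#' For every grid and channel the `ph x pw` feature patch `F` is scored
#' against its own transpose: `att = softmax(F %*% t(F) / sqrt(d_k))` with
#' `d_k = pw` (the grid width), the softmax taken along rows. Each grid and
#' channel is handled independently.
#'
#' @param features Array `ph x pw x C x G` of grid features (`G` grids).
#' @param spec A [grid_spec()] (supplies `d_k = pw`).
#' @return Array `ph x ph x C x G` of row-stochastic attention matrices.
#' @export
grid_attention <- function(features, spec) {
  d <- dim(features)
  if (length(d) != 4) abort("grid_attention expects a 4-D feature array")
  dk <- spec$pw
  if (dk <= 0) abort("d_k = W/w must be positive")
  att <- array(0, c(d[1], d[1], d[3], d[4]))
  sdk <- sqrt(dk)
  for (g in seq_len(d[4])) {
    for (c in seq_len(d[3])) {
      f <- features[, , c, g]
      att[, , c, g] <- softmax_rows(tcrossprod(f, f) / sdk)
    }
  }
  att
}

# Backward of grid_attention + squeeze: given d(scalar) per (grid, channel),
# return gradient on the features. ds is a C x G matrix.
grid_attention_backward <- function(features, att, ds, spec) {
  d <- dim(features)
  p <- d[1]
  sdk <- sqrt(spec$pw)
  dF <- array(0, d)
  for (g in seq_len(d[4])) {
    for (c in seq_len(d[3])) {
      a <- att[, , c, g]
      da <- matrix(ds[c, g] / (p * p), p, p)  # mean over the p x p matrix
      dscore <- a * (da - rowSums(da * a))    # row-wise softmax backward
      f <- features[, , c, g]
      dF[, , c, g] <- (dscore + t(dscore)) %*% f / sdk
    }
  }
  dF
}

#' Squeeze attention matrices to per-grid channel weights
#'
#' Averages each `ph x ph` attention matrix to a single scalar per
#' (grid, channel), then broadcasts the scalar onto a `ph x pw` block of
#' ones, yielding the grid-wise weight map.
#'
#' @param att Array `ph x ph x C x G` from [grid_attention()].
#' @param spec A [grid_spec()].
#' @return A list with `scalars` (`C x G` matrix) and `map`
#'   (`ph x pw x C x G` array of constant blocks).
#' @export
squeeze_expand <- function(att, spec) {
  d <- dim(att)
  if (any(!is.finite(att))) abort("attention values must be finite")
  scalars <- matrix(colMeans(matrix(att, nrow = d[1] * d[2])),
                    nrow = d[3])
  map <- array(rep(as.vector(scalars), each = spec$ph * spec$pw),
               c(spec$ph, spec$pw, d[3], d[4]))
  list(scalars = scalars, map = map)
}

#' Reassemble grid weights and re-weight the image
#'
#' Places the per-grid weight blocks back into image layout (the reverse of
#' the partition), crops to the original size, and multiplies the original
#' image element-wise, producing the attention-weighted image.
#'
#' @param weights Output of [squeeze_expand()] (or its `map` array).
#' @param image The original `H x W x C` image.
#' @param spec A [grid_spec()].
#' @return Numeric array `H x W x C`.
#' @export
ungrid_and_weight <- function(weights, image, spec) {
  map <- if (is.list(weights)) weights$map else weights
  wfull <- ungrid(map, spec, crop = TRUE)
  wfull * image
}

# ---- trainable GWA module ---------------------------------------------------

# LGFE: shared 1x1-conv bottleneck C -> C*k_e -> C with batch norm and leaky
# ReLU after each convolution, applied to all grids as one batch.
make_lgfe <- function(C, k_e = 4L) {
  hid <- C * k_e
  nn_sequential(
    nn_conv2d(C, hid, 1, 1), nn_batchnorm(hid), nn_act("leaky_relu"),
    nn_conv2d(hid, C, 1, 1), nn_batchnorm(C), nn_act("leaky_relu"))
}

gwa_module <- function(spec, k_e = 4L) {
  structure(list(spec = spec, lgfe = make_lgfe(spec$C, k_e),
                 cache = new.env(parent = emptyenv())),
            class = "hmhn_gwa")
}

# Batched partition: (H, W, C, N) -> (ph, pw, C, G*N), grid index fastest.
partition_batch <- function(x, spec) {
  xp <- pad_image(x, spec)
  d <- dim(xp)
  h <- spec$h; w <- spec$w; ph <- spec$ph; pw <- spec$pw
  G <- h * w
  out <- array(0, c(ph, pw, spec$C, G * d[4]))
  for (n in seq_len(d[4])) {
    g <- 0L
    for (i in seq_len(h)) for (j in seq_len(w)) {
      g <- g + 1L
      out[, , , (n - 1L) * G + g] <-
        xp[(i - 1L) * ph + seq_len(ph), (j - 1L) * pw + seq_len(pw), , n]
    }
  }
  out
}

# Forward over a batch: x (H, W, C, N) -> weighted image (H, W, C, N).
gwa_forward <- function(mod, x, train = TRUE) {
  spec <- mod$spec
  N <- dim(x)[4]
  G <- spec$h * spec$w
  grids <- partition_batch(x, spec)
  feats <- seq_forward(mod$lgfe, grids, train)
  att <- grid_attention(feats, spec)
  sq <- squeeze_expand(att, spec)             # scalars C x (G*N)
  wmap <- array(0, c(spec$H, spec$W, spec$C, N))
  for (n in seq_len(N)) {
    cols <- (n - 1L) * G + seq_len(G)
    wmap[, , , n] <- ungrid(sq$map[, , , cols, drop = FALSE], spec,
                            crop = TRUE)
  }
  cc <- mod$cache
  cc$feats <- feats; cc$att <- att; cc$x <- x; cc$wmap <- wmap
  wmap * x
}

# Backward: dy is the gradient on the weighted image. Accumulates LGFE
# parameter gradients; the gradient on the raw image is not propagated
# further (nothing trainable sits upstream of the input).
gwa_backward <- function(mod, dy) {
  spec <- mod$spec
  cc <- mod$cache
  N <- dim(dy)[4]
  G <- spec$h * spec$w
  dwmap <- dy * cc$x
  # gradient on each (grid, channel) scalar: sum over that grid's block,
  # restricted to the cropped (unpadded) region
  ds <- matrix(0, spec$C, G * N)
  for (n in seq_len(N)) {
    for (i in seq_len(spec$h)) for (j in seq_len(spec$w)) {
      g <- (i - 1L) * spec$w + j
      rows <- intersect((i - 1L) * spec$ph + seq_len(spec$ph), seq_len(spec$H))
      cols <- intersect((j - 1L) * spec$pw + seq_len(spec$pw), seq_len(spec$W))
      blk <- dwmap[rows, cols, , n, drop = FALSE]
      ds[, (n - 1L) * G + g] <- colSums(matrix(blk, ncol = spec$C))
    }
  }
  dF <- grid_attention_backward(cc$feats, cc$att, ds, spec)
  seq_backward(mod$lgfe, dF, need_dx = FALSE)
  dg_direct <- dy * cc$wmap
  cc$feats <- NULL; cc$att <- NULL; cc$x <- NULL; cc$wmap <- NULL
  dg_direct
}
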