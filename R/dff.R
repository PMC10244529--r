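# Deep feature fusion (DFF): two feature-transformation networks of
# identical architecture but independent parameters map the raw image and
# the grid-attention-weighted image into a common space; their sum passes
# through a small fusion network before entering the backbone. All three
# nets preserve the image shape so the element-wise sum is well-typed.

make_ft <- function(C = 3L, hidden = 16L) {
  nn_sequential(
    nn_conv2d(C, hidden, 3, 3, pad = c(1L, 1L)), nn_batchnorm(hidden),
    nn_act("leaky_relu"),
    nn_conv2d(hidden, C, 3, 3, pad = c(1L, 1L)), nn_batchnorm(C),
    nn_act("leaky_relu"))
}

make_fusion <- function(C = 3L) {
  nn_sequential(nn_conv2d(C, C, 1, 1), nn_batchnorm(C),
                nn_act("leaky_relu"))
}

dff_module <- function(C = 3L, ft_hidden = 16L) {
  structure(list(ft1 = make_ft(C, ft_hidden), ft2 = make_ft(C, ft_hidden),
                 fusion = make_fusion(C)),
            class = "hmhn_dff")
}

# g: raw image batch; g_tilde: GWA-weighted batch (same shape).
dff_forward <- function(mod, g, g_tilde, train = TRUE) {
  if (!identical(dim(g), dim(g_tilde)))
    abort("dff_forward: g and g_tilde must have identical shapes")
  if (inherits(mod, "hmhn_fast_dff"))
    return(cpp_dff_forward(mod$ptr, g, g_tilde, as.integer(dim(g)), train))
  a1 <- seq_forward(mod$ft1, g, train)
  a2 <- seq_forward(mod$ft2, g_tilde, train)
  seq_forward(mod$fusion, a1 + a2, train)
}

# Returns the gradient on g_tilde (flows back into GWA); the raw-image
# branch has no trainable modules upstream, so its input gradient stops at
# FT1's parameters.
dff_backward <- function(mod, dy) {
  if (inherits(mod, "hmhn_fast_dff"))
    return(cpp_dff_backward(mod$ptr, dy))
  ds <- seq_backward(mod$fusion, dy)
  seq_backward(mod$ft1, ds, need_dx = FALSE)
  seq_backward(mod$ft2, ds)
}

dff_layers <- function(mod) {
  if (inherits(mod, "hmhn_fast_dff")) return(list())
  c(seq_layers(mod$ft1), seq_layers(mod$ft2), seq_layers(mod$fusion))
}

dff_n_params <- function(mod) {
  if (inherits(mod, "hmhn_fast_dff"))
    return(cpp_dff_count_params(mod$ptr))
  sum(vapply(dff_layers(mod), n_params_layer, 0))
}
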