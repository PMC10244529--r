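# Seeded generator of face-like images whose geometry encodes a latent
# BDI-II score. The cues follow the clinical description of depressed
# facial appearance: the mouth curvature flattens into a frown and droops,
# the eyes narrow, and the brows tilt upward at the inner ends, each as an
# affine, strictly monotone function of the score. Rendering is pure
# arithmetic on a pixel grid, so images are bit-reproducible from
# (seed, score).

#' Synthetic face generator configuration
#'
#' Geometry coefficients of the score-dependent facial cues. With score
#' `s` scaled to `t = s/63`: mouth curvature `c = c0 - alpha * t`
#' (positive = smile), mouth droop `droop = delta * t`, eye openness
#' `o = o0 - beta * t`, brow angle `a = a0 + gamma * t` (radians; positive
#' tilts the inner brow ends upward). All are affine and strictly monotone
#' in `s`. These are artifact choices that make the dataset learnable at
#' desk scale, not values from any clinical source.
#'
#' @param size Image side length in pixels (square output).
#' @param c0,alpha Mouth curvature intercept/slope.
#' @param delta Mouth droop slope (vertical shift, unit coordinates).
#' @param o0,beta Eye openness intercept/slope.
#' @param a0,gamma Brow angle intercept/slope (radians).
#' @param jitter_px Maximum absolute translation jitter, pixels.
#' @param jitter_deg Maximum absolute rotation jitter, degrees.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @return A list of class `hmhn_synth_config`.
#' @export
synth_config <- function(size = 224L, c0 = 0.35, alpha = 0.7, delta = 0.10,
                         o0 = 1.0, beta = 0.55, a0 = -0.15, gamma = 0.5,
                         jitter_px = 8, jitter_deg = 10, noise_sd = 0.02) {
  structure(list(size = as.integer(size), c0 = c0, alpha = alpha,
                 delta = delta, o0 = o0, beta = beta, a0 = a0,
                 gamma = gamma, jitter_px = jitter_px,
                 jitter_deg = jitter_deg, noise_sd = noise_sd),
            class = "hmhn_synth_config")
}

#' Score-dependent face parameters
#'
#' @param score BDI-II score in \[0, 63\].
#' @param config A [synth_config()].
#' @return List with `score`, `curvature`, `droop`, `openness`,
#'   `brow_angle`.
#' @export
face_params <- function(score, config = synth_config()) {
  if (!is.numeric(score) || length(score) != 1 || !is.finite(score))
    abort("score must be a single finite number")
  if (score < 0 || score > 63) abort("score must lie in [0, 63]")
  t <- score / 63
  list(score = score,
       curvature = config$c0 - config$alpha * t,
       droop = config$delta * t,
       openness = config$o0 - config$beta * t,
       brow_angle = config$a0 + config$gamma * t)
}

# geometry constants (unit coordinates, v grows downward)
synth_geom <- list(
  face = c(rx = 0.72, ry = 0.92),
  eye_u = 0.28, eye_v = -0.22, eye_rx = 0.13, eye_ry = 0.07,
  brow_u = 0.28, brow_v = -0.40, brow_len = 0.13, brow_thick = 0.022,
  mouth_v0 = 0.45, mouth_w = 0.30, mouth_h = 0.30, mouth_thick = 0.035,
  col_bg = c(0.70, 0.72, 0.75), col_face = c(0.92, 0.78, 0.66),
  col_eye = c(0.10, 0.10, 0.12), col_brow = c(0.25, 0.18, 0.12),
  col_mouth = c(0.55, 0.15, 0.15))

# Deterministic rendering given explicit pose; the (H, W, C) image in
# [0, 1] before noise.
render_face <- function(params, config = synth_config(),
                        rot = 0, tx = 0, ty = 0) {
  S <- config$size
  g <- synth_geom
  ax <- seq(-1, 1, length.out = S)
  u0 <- matrix(ax, S, S, byrow = TRUE)   # column coordinate
  v0 <- matrix(ax, S, S)                 # row coordinate, downward
  cs <- cos(rot); sn <- sin(rot)
  u <- cs * (u0 - tx) + sn * (v0 - ty)
  v <- -sn * (u0 - tx) + cs * (v0 - ty)

  img <- array(0, c(S, S, 3))
  paint <- function(mask, col) {
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[mask] <- col[ch]
      img[, , ch] <<- pl
    }
  }
  paint(matrix(TRUE, S, S), g$col_bg)
  paint((u / g$face["rx"])^2 + (v / g$face["ry"])^2 <= 1, g$col_face)

  ery <- g$eye_ry * params$openness
  for (sgn in c(-1, 1)) {
    eye <- ((u - sgn * g$eye_u) / g$eye_rx)^2 +
           ((v - g$eye_v) / ery)^2 <= 1
    paint(eye, g$col_eye)
    phi <- -sgn * params$brow_angle
    du <- u - sgn * g$brow_u
    dv <- v - g$brow_v
    lu <- du * cos(phi) + dv * sin(phi)
    lv <- -du * sin(phi) + dv * cos(phi)
    paint(abs(lu) <= g$brow_len & abs(lv) <= g$brow_thick, g$col_brow)
  }

  vm <- g$mouth_v0 + params$droop +
    params$curvature * g$mouth_h * (0.5 - (u / g$mouth_w)^2)
  mouth <- abs(v - vm) <= g$mouth_thick & abs(u) <= g$mouth_w
  paint(mouth, g$col_mouth)
  img
}

# evaluate code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate one synthetic face
#'
#' Renders the face for `score` with seeded pose jitter (translation up to
#' `jitter_px` pixels, rotation up to `jitter_deg` degrees) and Gaussian
#' pixel noise, clipped to \[0, 1\]. Bit-reproducible from `(seed, score)`.
#'
#' @param seed Integer seed for jitter and noise.
#' @param score BDI-II score in \[0, 63\].
#' @param config A [synth_config()].
#' @return List with `image` (`size` x `size` x 3 array in \[0, 1\]) and
#'   `params` ([face_params()]).
#' @examples
#' s <- generate_sample(1, 44)
#' dim(s$image)
#' @export
generate_sample <- function(seed, score, config = synth_config()) {
  params <- face_params(score, config)
  S <- config$size
  img <- with_seed(as.integer(seed), {
    jp <- config$jitter_px / (S / 2)
    tx <- stats::runif(1, -jp, jp)
    ty <- stats::runif(1, -jp, jp)
    rot <- stats::runif(1, -config$jitter_deg, config$jitter_deg) * pi / 180
    out <- render_face(params, config, rot = rot, tx = tx, ty = ty)
    if (config$noise_sd > 0)
      out <- out + array(stats::rnorm(length(out), sd = config$noise_sd),
                         dim(out))
    out
  })
  list(image = pmin(pmax(img, 0), 1), params = params)
}

#' Right-skewed default score sampler
#'
#' Draws `Beta(shape1, shape2) * 63`; the default (1.2, 2.5) concentrates
#' mass at low scores, mimicking the skew of clinical score distributions.
#'
#' @param n Number of draws.
#' @param shape1,shape2 Beta shape parameters.
#' @return Numeric vector of scores in \[0, 63\].
#' @export
score_sampler_beta <- function(n, shape1 = 1.2, shape2 = 2.5) {
  rbeta(n, shape1, shape2) * 63
}

#' Generate a synthetic dataset on disk
#'
#' Samples `n` scores from `dist`, renders each face with its own
#' deterministic per-sample seed (`seed + index`), writes PNGs and a
#' manifest CSV (`path`, `bdi2_score`, `split`) to `out_dir`. Samples are
#' assigned to the train/dev/test splits in order, with counts given by
#' the normalized `splits` proportions.
#'
#' @param n Number of images (>= 1).
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if missing).
#' @param dist Score sampler, a `function(n)`; defaults to
#'   [score_sampler_beta()].
#' @param splits Named proportions for `train`, `dev`, `test`.
#' @param config A [synth_config()].
#' @return The manifest as a tibble, invisibly also written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(n, seed, out_dir, dist = score_sampler_beta,
                             splits = c(train = 0.7, dev = 0.15,
                                        test = 0.15),
                             config = synth_config()) {
  if (n < 1) abort("n must be >= 1")
  if (!all(c("train", "dev", "test") %in% names(splits)))
    abort("splits must name train, dev and test")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    abort(sprintf("cannot create output directory '%s'", out_dir))
  scores <- with_seed(as.integer(seed), dist(n))
  scores <- pmin(pmax(scores, 0), 63)
  p <- splits[c("train", "dev", "test")] / sum(splits)
  n_train <- round(n * p[["train"]])
  n_dev <- round(n * p[["dev"]])
  split <- rep(c("train", "dev", "test"),
               c(n_train, n_dev, n - n_train - n_dev))
  path <- sprintf("img_%05d.png", seq_len(n))
  for (i in seq_len(n)) {
    s <- generate_sample(as.integer(seed) + i, scores[i], config)
    png::writePNG(s$image, file.path(out_dir, path[i]))
  }
  manifest <- tibble(path = path, bdi2_score = scores, split = split)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Mouth-region intensity of noise-free renders
#'
#' Average pixel intensity inside a fixed mouth region for jitter- and
#' noise-free renders of the given scores. The region is a band that the
#' mouth gradually leaves as it droops and flattens with rising score, so
#' the intensity is strictly monotone in the score.
#'
#' @param scores Numeric vector of scores in \[0, 63\].
#' @param config A [synth_config()].
#' @return Tibble with `score` and `intensity`.
#' @export
mouth_signal <- function(scores, config = synth_config()) {
  S <- config$size
  g <- synth_geom
  ax <- seq(-1, 1, length.out = S)
  rows <- which(ax >= g$mouth_v0 - 0.20 & ax <= g$mouth_v0 + 0.05)
  cols <- which(abs(ax) <= g$mouth_w * 1.2)
  intensity <- vapply(scores, function(s) {
    img <- render_face(face_params(s, config), config)
    mean(img[rows, cols, ])
  }, 0)
  tibble(score = scores, intensity = intensity)
}
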