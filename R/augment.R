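# Lesion-safe RandAugment-style augmentation ("AcneAugment").
#
# A policy is an active set of transforms, each with a magnitude-scaling
# coefficient, plus the (N, M) pair: N transforms are drawn uniformly with
# replacement and applied in sequence at strength (M/10) * scale *
# per-transform maximum range. Color-disruptive transforms (color,
# contrast, invert, posterize, solarize, sharpness) and lesion-mixing
# (sample pairing) carry scale 0 in the default preset and are never
# sampled, because lesion appearance is chromatically fragile.
#
# Per-transform semantics of the scale coefficient (the source tables give
# only the coefficient, so units are fixed here):
#   Rotate:        max angle  = scale * 30 degrees, random sign
#   Shear-x/y:     max shear  = scale * 0.30, random sign
#   Translate-x/y: max shift  = scale * 0.33 of the image extent, random sign
#   Brightness/Color/Contrast/Sharpness: max enhancement delta = scale * 0.9,
#                  random sign (factor 1 + delta)
#   AutoContrast/Equalize/Invert (parameterless ops): blend weight
#                  alpha = (M/10) * scale between the original and the
#                  fully-applied op
#   Posterize:     bits = 8 - round(4 * strength); Solarize: threshold =
#                  1 - strength. Negative coefficients (RA presets) follow
#                  the inverted-magnitude convention: strength grows as M
#                  decreases.
# Geometric transforms use bilinear interpolation with reflection padding
# and preserve image dimensions.

.aa_presets <- list(
  aa = c(autocontrast = 0.1, brightness = 0.1, color = 0.0, contrast = 0.0,
         equalize = 0.3, invert = 0.0, sharpness = 0.0, posterize = 0.0,
         solarize = 0.0, rotate = 1.3, shear_x = 0.9, shear_y = 0.9,
         translate_x = 0.9, translate_y = 0.9, sample_pairing = 0.0),
  ra_cifar = c(autocontrast = 0.1, brightness = 0.0, color = 0.0,
               contrast = 0.0, equalize = 0.1, invert = 0.1, sharpness = 0.1,
               posterize = -0.3, solarize = -0.1, rotate = 1.3,
               shear_x = 0.9, shear_y = 0.9, translate_x = 0.4,
               translate_y = 0.4, sample_pairing = 0.1),
  ra_svhn = c(autocontrast = 0.1, brightness = 0.0, color = 0.0,
              contrast = 0.0, equalize = 0.1, invert = 0.1, sharpness = 0.1,
              posterize = -0.3, solarize = -0.1, rotate = 0.0,
              shear_x = 0.9, shear_y = 0.9, translate_x = 0.0,
              translate_y = 0.4, sample_pairing = 0.0)
)

#' Build an augmentation policy
#'
#' @param preset `"aa"` (lesion-safe default), `"ra_cifar"` or `"ra_svhn"`.
#' @param overrides named numeric vector of scale overrides (>= 0 sets or
#'   replaces a coefficient; 0 removes the transform from the active set).
#' @param n_ops number N of transforms applied per image.
#' @param magnitude integer M in 1..10.
#' @return object of class `"aa_policy"`: the active (name, scale) table
#'   plus (N, M).
#' @export
aa_policy <- function(preset = c("aa", "ra_cifar", "ra_svhn"),
                      overrides = NULL, n_ops = 2L, magnitude = 9L) {
  preset <- match.arg(preset)
  sc <- .aa_presets[[preset]]
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(sc))
    if (length(bad)) stop("unknown transform name: ", paste(bad, collapse = ", "))
    sc[names(overrides)] <- overrides
  }
  stopifnot(n_ops >= 0L, magnitude >= 1L, magnitude <= 10L)
  active <- sc[sc != 0]
  structure(list(transforms = active, n_ops = as.integer(n_ops),
                 magnitude = as.integer(magnitude), preset = preset),
            class = "aa_policy")
}

#' @export
print.aa_policy <- function(x, ...) {
  cat(sprintf("<aa_policy preset=%s N=%d M=%d>\n", x$preset, x$n_ops,
              x$magnitude))
  print(x$transforms)
  invisible(x)
}

#' The (N, M) grid-search space of the policy
#'
#' @return data frame of the exactly 100 pairs `N` in 1..10 by `M` in 1..10.
#' @export
aa_policy_grid <- function() {
  expand.grid(N = 1:10, M = 1:10)
}

# ---- geometry: inverse affine map with bilinear + reflection padding -----

reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1, length(i)))
  p <- 2 * (n - 1)
  j <- (i - 1) %% p   # R's %% is already nonnegative for positive modulus
  pmin(j, p - j) + 1
}

# Apply the inverse-affine sample: for each output pixel, source coords
# come from the 2x2 matrix A and offset t (about the image center).
affine_sample <- function(img, A, tvec) {
  H <- dim(img)[1L]; W <- dim(img)[2L]; C <- dim(img)[3L]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yo <- rep(seq_len(H), times = W) - cy
  xo <- rep(seq_len(W), each = H) - cx
  ys <- A[1, 1] * yo + A[1, 2] * xo + tvec[1] + cy
  xs <- A[2, 1] * yo + A[2, 2] * xo + tvec[2] + cx
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  iy0 <- reflect_index(y0, H); iy1 <- reflect_index(y0 + 1, H)
  ix0 <- reflect_index(x0, W); ix1 <- reflect_index(x0 + 1, W)
  i00 <- iy0 + (ix0 - 1) * H; i10 <- iy1 + (ix0 - 1) * H
  i01 <- iy0 + (ix1 - 1) * H; i11 <- iy1 + (ix1 - 1) * H
  out <- array(0, dim(img))
  for (ch in seq_len(C)) {
    M <- img[, , ch]
    v <- (1 - fy) * (1 - fx) * M[i00] + fy * (1 - fx) * M[i10] +
      (1 - fy) * fx * M[i01] + fy * fx * M[i11]
    out[, , ch] <- matrix(v, H, W)
  }
  out
}

# ---- individual transforms ----------------------------------------------

clip01 <- function(x) pmin(pmax(x, 0), 1)

tf_autocontrast <- function(img, alpha) {
  out <- img
  for (ch in seq_len(dim(img)[3L])) {
    m <- min(img[, , ch]); M <- max(img[, , ch])
    if (M > m) out[, , ch] <- (img[, , ch] - m) / (M - m)
  }
  clip01((1 - alpha) * img + alpha * out)
}

tf_equalize <- function(img, alpha) {
  out <- img
  for (ch in seq_len(dim(img)[3L])) {
    v <- img[, , ch]
    q <- as.integer(round(v * 255))
    cdf <- cumsum(tabulate(q + 1L, 256L))
    cdf <- (cdf - cdf[min(q) + 1L]) / max(1L, length(v) - cdf[min(q) + 1L])
    out[, , ch] <- matrix(cdf[q + 1L], dim(img)[1L], dim(img)[2L])
  }
  clip01((1 - alpha) * img + alpha * out)
}

tf_invert <- function(img, alpha) clip01((1 - alpha) * img + alpha * (1 - img))

tf_brightness <- function(img, delta) clip01(img * (1 + delta))

tf_color <- function(img, delta) {
  gray <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
  out <- img
  for (ch in 1:3) out[, , ch] <- gray + (1 + delta) * (img[, , ch] - gray)
  clip01(out)
}

tf_contrast <- function(img, delta) {
  mu <- mean(img)
  clip01(mu + (1 + delta) * (img - mu))
}

tf_sharpness <- function(img, delta) {
  # unsharp-mask style: blend with a 3x3 box blur
  H <- dim(img)[1L]; W <- dim(img)[2L]
  blur <- img
  for (ch in seq_len(dim(img)[3L])) {
    M <- img[, , ch]
    P <- M[c(1, 1:(H - 1)), ] + M + M[c(2:H, H), ]
    B <- (P[, c(1, 1:(W - 1))] + P + P[, c(2:W, W)]) / 9
    blur[, , ch] <- B
  }
  clip01(img + delta * (img - blur))
}

tf_posterize <- function(img, strength) {
  bits <- max(1L, 8L - as.integer(round(4 * strength)))
  lv <- 2^bits
  clip01(floor(img * (lv - 1) + 0.5) / (lv - 1))
}

tf_solarize <- function(img, strength) {
  thr <- 1 - strength
  ifelse(img >= thr, 1 - img, img) * 1
}

tf_rotate <- function(img, angle_deg) {
  a <- angle_deg * pi / 180
  # inverse rotation
  A <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
  affine_sample(img, A, c(0, 0))
}

tf_shear <- function(img, axis, shear) {
  A <- diag(2)
  if (axis == "x") A[2, 1] <- -shear else A[1, 2] <- -shear
  affine_sample(img, A, c(0, 0))
}

tf_translate <- function(img, axis, frac) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  tvec <- if (axis == "x") c(0, -frac * W) else c(-frac * H, 0)
  affine_sample(img, diag(2), tvec)
}

tf_sample_pairing <- function(img, alpha, pair = NULL) {
  if (is.null(pair)) pair <- img[, rev(seq_len(dim(img)[2L])), , drop = FALSE]
  clip01((1 - alpha) * img + alpha * pair)
}

apply_one_transform <- function(img, name, scale, magnitude, pair = NULL) {
  frac <- magnitude / 10
  # negative coefficients use the inverted-magnitude convention
  strength <- if (scale < 0) (1 - frac) * abs(scale) else frac * scale
  # signed ops get the full strength with a random sign
  draw <- function(maxv) {
    s <- if (stats::runif(1) < 0.5) -1 else 1
    s * strength * maxv
  }
  switch(name,
    autocontrast = tf_autocontrast(img, strength),
    equalize = tf_equalize(img, strength),
    invert = tf_invert(img, strength),
    brightness = tf_brightness(img, draw(0.9)),
    color = tf_color(img, draw(0.9)),
    contrast = tf_contrast(img, draw(0.9)),
    sharpness = tf_sharpness(img, draw(0.9)),
    posterize = tf_posterize(img, strength),
    solarize = tf_solarize(img, strength),
    rotate = tf_rotate(img, draw(30)),
    shear_x = tf_shear(img, "x", draw(0.3)),
    shear_y = tf_shear(img, "y", draw(0.3)),
    translate_x = tf_translate(img, "x", draw(0.33)),
    translate_y = tf_translate(img, "y", draw(0.33)),
    sample_pairing = tf_sample_pairing(img, strength, pair),
    stop("unknown transform: ", name)
  )
}

#' Apply an augmentation policy to one image
#'
#' Draws `policy$n_ops` transforms uniformly with replacement from the
#' active set and applies them in order. Uses the current R random stream;
#' pass `seed` for a self-contained deterministic call (the global stream
#' is restored afterwards). Output dimensions always equal input
#' dimensions.
#'
#' @param img H x W x C array in \[0, 1\].
#' @param policy an [aa_policy()].
#' @param seed optional integer seed.
#' @param pair optional second image for the sample-pairing transform.
#' @return augmented image with attribute `"ops"` listing the applied
#'   transform names.
#' @export
aa_apply <- function(img, policy, seed = NULL, pair = NULL) {
  stopifnot(is.array(img), length(dim(img)) == 3L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)
  }
  nm <- names(policy$transforms)
  ops <- character(0)
  if (policy$n_ops > 0L && length(nm) > 0L) {
    ops <- nm[sample.int(length(nm), policy$n_ops, replace = TRUE)]
    for (op in ops) {
      img <- apply_one_transform(img, op, policy$transforms[[op]],
                                 policy$magnitude, pair = pair)
    }
  }
  attr(img, "ops") <- ops
  img
}
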