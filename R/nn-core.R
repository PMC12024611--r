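# Minimal layer engine with explicit per-parameter gradients.
#
# The teacher-student feedback chain needs raw gradient vectors (inner
# products across all parameters, gradients re-evaluated at shifted
# parameter values), so every layer here exposes a paired forward/backward
# with an explicit cache instead of hiding state in an autodiff graph.
#
# Feature maps are stored as a list(x, H, W, N): `x` is a (N*H*W) x C
# matrix whose rows are ordered image-major, then spatially column-major
# (row index within an image = y + (x-1)*H), matching R's native array
# layout so images convert with a plain as.vector().

fmap <- function(x, H, W, N) list(x = x, H = H, W = W, N = N)

#' @noRd
images_to_fmap <- function(imgs) {
  # imgs: list of HxWxC arrays (all same size) or a single HxWxC array
  if (is.array(imgs) && length(dim(imgs)) == 3L) imgs <- list(imgs)
  d <- dim(imgs[[1L]])
  H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- length(imgs)
  x <- matrix(0, N * H * W, C)
  for (n in seq_len(N)) {
    rows <- ((n - 1L) * H * W + 1L):(n * H * W)
    x[rows, ] <- matrix(imgs[[n]], H * W, C)
  }
  fmap(x, H, W, N)
}

fmap_to_images <- function(fm) {
  lapply(seq_len(fm$N), function(n) {
    rows <- ((n - 1L) * fm$H * fm$W + 1L):(n * fm$H * fm$W)
    array(fm$x[rows, ], c(fm$H, fm$W, ncol(fm$x)))
  })
}

# ---- im2col index caches -------------------------------------------------

.conv_idx_cache <- new.env(parent = emptyenv())

# Patch-gather index for a zero-padded 3x3 (or kxk) convolution.
# Returns list(idx = integer vector addressing rows of rbind(x, 0),
#              Ho, Wo, kk) with the zero row at position N*H*W + 1.
conv_gather_idx <- function(H, W, N, k, stride, pad) {
  key <- paste(H, W, N, k, stride, pad, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  # map padded (yp, xp) -> source linear index or 0
  yp <- rep(seq_len(Hp), times = Wp)
  xp <- rep(seq_len(Wp), each = Hp)
  ys <- yp - pad; xs <- xp - pad
  inside <- ys >= 1L & ys <= H & xs >= 1L & xs <= W
  padmap <- ifelse(inside, ys + (xs - 1L) * H, 0L)
  # output position grid (column-major: yo fastest)
  yo <- rep(seq_len(Ho), times = Wo)
  xo <- rep(seq_len(Wo), each = Ho)
  kk <- k * k
  M <- matrix(0L, Ho * Wo, kk)
  j <- 0L
  for (kx in seq_len(k)) for (ky in seq_len(k)) {
    j <- j + 1L
    ypp <- (yo - 1L) * stride + ky
    xpp <- (xo - 1L) * stride + kx
    M[, j] <- padmap[ypp + (xpp - 1L) * Hp]
  }
  HW <- H * W
  zrow <- N * HW + 1L
  big <- matrix(0L, N * Ho * Wo, kk)
  for (n in seq_len(N)) {
    Mn <- M + (n - 1L) * HW
    Mn[M == 0L] <- zrow
    big[((n - 1L) * Ho * Wo + 1L):(n * Ho * Wo), ] <- Mn
  }
  idx <- as.integer(big)
  out <- list(idx = idx, uidx = sort.int(unique(idx)), Ho = Ho, Wo = Wo,
              kk = kk)
  .conv_idx_cache[[key]] <- out
  out
}

.up_idx_cache <- new.env(parent = emptyenv())

upsample_idx <- function(H, W, N) {
  key <- paste(H, W, N, sep = "_")
  hit <- .up_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- 2L * H; Wo <- 2L * W
  yo <- rep(seq_len(Ho), times = Wo)
  xo <- rep(seq_len(Wo), each = Ho)
  src <- ((yo + 1L) %/% 2L) + (((xo + 1L) %/% 2L) - 1L) * H
  idx <- integer(N * Ho * Wo)
  for (n in seq_len(N)) {
    idx[((n - 1L) * Ho * Wo + 1L):(n * Ho * Wo)] <- src + (n - 1L) * H * W
  }
  out <- list(idx = idx, uidx = sort.int(unique(idx)), Ho = Ho, Wo = Wo)
  .up_idx_cache[[key]] <- out
  out
}

# ---- primitive layers ----------------------------------------------------

conv_forward <- function(fm, W, b, stride = 1L, pad = 1L) {
  k <- as.integer(round(sqrt(nrow(W) / max(1L, ncol(fm$x)))))
  gi <- conv_gather_idx(fm$H, fm$W, fm$N, k, as.integer(stride), as.integer(pad))
  Xz <- rbind(fm$x, 0)
  P <- matrix(Xz[gi$idx, ], fm$N * gi$Ho * gi$Wo, gi$kk * ncol(fm$x))
  out <- P %*% W
  out <- sweep(out, 2L, b, "+")
  list(out = fmap(out, gi$Ho, gi$Wo, fm$N),
       cache = list(P = P, gi = gi, in_rows = nrow(fm$x), Cin = ncol(fm$x),
                    H = fm$H, W = fm$W, N = fm$N))
}

conv_backward <- function(cache, W, dout) {
  dW <- crossprod(cache$P, dout$x)
  db <- colSums(dout$x)
  dP <- dout$x %*% t(W)
  dPr <- matrix(dP, length(cache$gi$idx), cache$Cin)
  acc <- rowsum(dPr, cache$gi$idx, reorder = TRUE)
  dX <- matrix(0, cache$in_rows + 1L, cache$Cin)
  dX[cache$gi$uidx, ] <- acc
  dX <- dX[-(cache$in_rows + 1L), , drop = FALSE]
  list(dinput = fmap(dX, cache$H, cache$W, cache$N), dW = dW, db = db)
}

relu_forward <- function(x) {
  out <- x * (x > 0)
  list(out = out, cache = x > 0)
}
relu_backward <- function(cache, dout) dout * cache

sigmoid_forward <- function(x) {
  out <- 1 / (1 + exp(-x))
  list(out = out, cache = out)
}
sigmoid_backward <- function(cache, dout) dout * cache * (1 - cache)

# Batch normalization over all rows of a feature-map matrix, per channel.
bn_forward <- function(x, gamma, beta, run_mean, run_var, momentum, training,
                       eps = 1e-5) {
  if (training) {
    m <- nrow(x)
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    v <- pmax(v, 0)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v * m / max(1, m - 1)
  } else {
    mu <- run_mean; v <- run_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2L, mu, "-"), 2L, invstd, "*")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                    training = training),
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(cache, dout) {
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, cache$gamma, "*")
  if (cache$training) {
    m <- nrow(dout)
    t1 <- sweep(dxhat, 2L, colMeans(dxhat), "-")
    t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
    dx <- sweep(t1 - t2, 2L, cache$invstd, "*")
  } else {
    dx <- sweep(dxhat, 2L, cache$invstd, "*")
  }
  list(dinput = dx, dgamma = dgamma, dbeta = dbeta)
}

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= rate) / (1 - rate)
  list(out = x * mask, cache = mask)
}
dropout_backward <- function(cache, dout) {
  if (is.null(cache)) dout else dout * cache
}

upsample_forward <- function(fm) {
  ui <- upsample_idx(fm$H, fm$W, fm$N)
  list(out = fmap(fm$x[ui$idx, , drop = FALSE], ui$Ho, ui$Wo, fm$N),
       cache = list(ui = ui, H = fm$H, W = fm$W, N = fm$N,
                    in_rows = nrow(fm$x)))
}
upsample_backward <- function(cache, dout) {
  acc <- rowsum(dout$x, cache$ui$idx, reorder = TRUE)
  dX <- matrix(0, cache$in_rows, ncol(dout$x))
  dX[cache$ui$uidx, ] <- acc
  fmap(dX, cache$H, cache$W, cache$N)
}

# Global average pool: fmap -> N x C matrix
gap_forward <- function(fm) {
  grp <- rep(seq_len(fm$N), each = fm$H * fm$W)
  out <- rowsum(fm$x, grp) / (fm$H * fm$W)
  list(out = out, cache = list(H = fm$H, W = fm$W, N = fm$N))
}
gap_backward <- function(cache, dout) {
  dX <- dout[rep(seq_len(cache$N), each = cache$H * cache$W), , drop = FALSE] /
    (cache$H * cache$W)
  fmap(dX, cache$H, cache$W, cache$N)
}

dense_forward <- function(x, W, b) {
  out <- sweep(x %*% W, 2L, b, "+")
  list(out = out, cache = x)
}
dense_backward <- function(cache, W, dout) {
  list(dinput = dout %*% t(W), dW = crossprod(cache, dout), db = colSums(dout))
}

# ---- parameter helpers ---------------------------------------------------

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Flatten a nested parameter/gradient list into one numeric vector
#' @noRd
flatten_params <- function(p) unlist(p, use.names = FALSE)

#' Inner product of two parameter lists with identical structure
#' @noRd
param_dot <- function(a, b) {
  sum(mapply(function(x, y) sum(x * y), a, b))
}

param_axpy <- function(p, g, alpha) {
  # p + alpha * g, elementwise over the list structure
  mapply(function(x, y) x + alpha * y, p, g, SIMPLIFY = FALSE)
}

param_zero <- function(p) lapply(p, function(x) x * 0)

stopifnot_finite <- function(p, what) {
  ok <- all(vapply(p, function(x) all(is.finite(x)), logical(1L)))
  if (!ok) stop(sprintf("non-finite values in %s: training diverged", what),
                call. = FALSE)
  invisible(TRUE)
}
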