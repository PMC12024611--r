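# Facial-skin segmentation (AFSS): a LinkNet-style encoder-decoder that
# labels skin vs non-skin pixels and crops images to the skin region.
#
# Five stride-2 stages (an input stem plus four encoder blocks) downsample
# by 32; four decoder blocks upsample back, each fused *additively* with
# the matching encoder feature map (LinkNet's link propagation), and a
# final stage restores full resolution with a sigmoid skin-probability
# map. At width = 1 the encoder/decoder channel pairs are exactly
# (64,64),(64,128),(128,256),(256,512) and (64,64),(128,64),(256,128),
# (512,256); smaller widths scale every channel count proportionally for
# desk-scale training.

#' Construct the skin-segmentation network
#'
#' @param in_channels input image channels.
#' @param width channel-width multiplier; `1` reproduces the reference
#'   channel table, fractions give proportionally slimmer models.
#' @param bn_momentum running-statistics momentum of the batch-norm layers.
#' @return object of class `"afss_model"`.
#' @export
build_afss <- function(in_channels = 3L, width = 1, bn_momentum = 0.99) {
  ch <- pmax(1L, as.integer(round(c(64, 128, 256, 512) * width)))
  c1 <- ch[1L]; c2 <- ch[2L]; c3 <- ch[3L]; c4 <- ch[4L]
  blocks <- list(
    init = c(in_channels, c1), enc1 = c(c1, c1), enc2 = c(c1, c2),
    enc3 = c(c2, c3), enc4 = c(c3, c4),
    dec4 = c(c4, c3), dec3 = c(c3, c2), dec2 = c(c2, c1), dec1 = c(c1, c1)
  )
  params <- list(); buffers <- list()
  for (nm in names(blocks)) {
    cin <- blocks[[nm]][1L]; cout <- blocks[[nm]][2L]
    params[[paste0(nm, "_W")]] <- he_init(9L * cin, cout, 9L * cin)
    params[[paste0(nm, "_b")]] <- numeric(cout)
    params[[paste0(nm, "_g")]] <- rep(1, cout)
    params[[paste0(nm, "_be")]] <- numeric(cout)
    buffers[[paste0(nm, "_rm")]] <- numeric(cout)
    buffers[[paste0(nm, "_rv")]] <- rep(1, cout)
  }
  params$final_W <- he_init(9L * c1, 1L, 9L * c1)
  params$final_b <- numeric(1L)
  structure(list(in_channels = as.integer(in_channels), width = width,
                 channels = c(c1, c2, c3, c4), bn_momentum = bn_momentum,
                 params = params, buffers = buffers,
                 history = NULL),
            class = "afss_model")
}

#' Channel audit of the segmentation architecture
#'
#' @param model an `"afss_model"`.
#' @return data frame with one row per block and the (in, out) channel
#'   pair of the encoder and decoder at that level.
#' @export
afss_architecture <- function(model) {
  ch <- model$channels
  data.frame(
    block = 1:4,
    encoder_in = c(ch[1L], ch[1L], ch[2L], ch[3L]),
    encoder_out = c(ch[1L], ch[2L], ch[3L], ch[4L]),
    decoder_in = c(ch[1L], ch[2L], ch[3L], ch[4L]),
    decoder_out = c(ch[1L], ch[1L], ch[2L], ch[3L])
  )
}

#' @export
print.afss_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1L)))
  cat(sprintf("<afss_model width=%.3g channels=%s params=%d>\n", x$width,
              paste(x$channels, collapse = "/"), np))
  invisible(x)
}

# one conv(+stride)/bn/relu block
afss_block_fwd <- function(fm, p, buf, nm, stride, momentum, training) {
  cf <- conv_forward(fm, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]],
                     stride = stride, pad = 1L)
  bf <- bn_forward(cf$out$x, p[[paste0(nm, "_g")]], p[[paste0(nm, "_be")]],
                   buf[[paste0(nm, "_rm")]], buf[[paste0(nm, "_rv")]],
                   momentum, training)
  buf[[paste0(nm, "_rm")]] <- bf$run_mean
  buf[[paste0(nm, "_rv")]] <- bf$run_var
  rf <- relu_forward(bf$out)
  list(out = fmap(rf$out, cf$out$H, cf$out$W, cf$out$N),
       cache = list(conv = cf$cache, bn = bf$cache, relu = rf$cache),
       buf = buf)
}

afss_block_bwd <- function(dout_fm, cache, p, nm, grads) {
  dx <- relu_backward(cache$relu, dout_fm$x)
  bb <- bn_backward(cache$bn, dx)
  grads[[paste0(nm, "_g")]] <- bb$dgamma
  grads[[paste0(nm, "_be")]] <- bb$dbeta
  cb <- conv_backward(cache$conv, p[[paste0(nm, "_W")]],
                      fmap(bb$dinput, dout_fm$H, dout_fm$W, dout_fm$N))
  grads[[paste0(nm, "_W")]] <- cb$dW
  grads[[paste0(nm, "_b")]] <- cb$db
  list(dinput = cb$dinput, grads = grads)
}

afss_forward <- function(model, fm, training = FALSE) {
  if (fm$H %% 32L != 0L || fm$W %% 32L != 0L)
    stop("input spatial dimensions must be divisible by 32 ",
         "(use segment_and_crop(), which pads automatically)")
  p <- model$params; buf <- model$buffers; mom <- model$bn_momentum
  enc <- list(); caches <- list()
  b <- afss_block_fwd(fm, p, buf, "init", 2L, mom, training)
  enc$init <- b$out; caches$init <- b$cache; buf <- b$buf
  b <- afss_block_fwd(enc$init, p, buf, "enc1", 2L, mom, training)
  enc$e1 <- b$out; caches$enc1 <- b$cache; buf <- b$buf
  b <- afss_block_fwd(enc$e1, p, buf, "enc2", 2L, mom, training)
  enc$e2 <- b$out; caches$enc2 <- b$cache; buf <- b$buf
  b <- afss_block_fwd(enc$e2, p, buf, "enc3", 2L, mom, training)
  enc$e3 <- b$out; caches$enc3 <- b$cache; buf <- b$buf
  b <- afss_block_fwd(enc$e3, p, buf, "enc4", 2L, mom, training)
  x <- b$out; caches$enc4 <- b$cache; buf <- b$buf

  skips <- list(dec4 = enc$e3, dec3 = enc$e2, dec2 = enc$e1, dec1 = enc$init)
  for (nm in c("dec4", "dec3", "dec2", "dec1")) {
    uf <- upsample_forward(x)
    caches[[paste0(nm, "_up")]] <- uf$cache
    b <- afss_block_fwd(uf$out, p, buf, nm, 1L, mom, training)
    caches[[nm]] <- b$cache; buf <- b$buf
    x <- b$out
    x$x <- x$x + skips[[nm]]$x   # additive feature fusion
  }
  uf <- upsample_forward(x)
  caches$final_up <- uf$cache
  cf <- conv_forward(uf$out, p$final_W, p$final_b, stride = 1L, pad = 1L)
  caches$final <- cf$cache
  sg <- sigmoid_forward(cf$out$x)
  caches$sig <- sg$cache
  list(prob = fmap(sg$out, cf$out$H, cf$out$W, cf$out$N), caches = caches,
       buffers = buf)
}

# backward from d(logit) at the final conv output
afss_backward <- function(model, caches, dlogit_fm) {
  p <- model$params
  grads <- list()
  cb <- conv_backward(caches$final, p$final_W, dlogit_fm)
  grads$final_W <- cb$dW; grads$final_b <- cb$db
  d <- upsample_backward(caches$final_up, cb$dinput)
  dskip <- list()
  for (nm in c("dec1", "dec2", "dec3", "dec4")) {
    # gradient entering the post-fusion map: split into block chain + skip
    dskip[[nm]] <- d
    bb <- afss_block_bwd(d, caches[[nm]], p, nm, grads)
    grads <- bb$grads
    d <- upsample_backward(caches[[paste0(nm, "_up")]], bb$dinput)
  }
  # d now holds the gradient wrt enc4 output
  bb <- afss_block_bwd(d, caches$enc4, p, "enc4", grads); grads <- bb$grads
  d <- bb$dinput; d$x <- d$x + dskip$dec4$x
  bb <- afss_block_bwd(d, caches$enc3, p, "enc3", grads); grads <- bb$grads
  d <- bb$dinput; d$x <- d$x + dskip$dec3$x
  bb <- afss_block_bwd(d, caches$enc2, p, "enc2", grads); grads <- bb$grads
  d <- bb$dinput; d$x <- d$x + dskip$dec2$x
  bb <- afss_block_bwd(d, caches$enc1, p, "enc1", grads); grads <- bb$grads
  d <- bb$dinput; d$x <- d$x + dskip$dec1$x
  bb <- afss_block_bwd(d, caches$init, p, "init", grads); grads <- bb$grads
  grads[names(model$params)]
}

seg_loss_grad <- function(prob, target, loss = c("bce", "dice")) {
  loss <- match.arg(loss)
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  n <- length(p)
  if (loss == "bce") {
    L <- -mean(target * log(p) + (1 - target) * log(1 - p))
    dlogit <- (p - target) / n
  } else {
    num <- 2 * sum(p * target); den <- sum(p) + sum(target) + 1e-7
    L <- 1 - num / den
    dp <- -(2 * target * den - num) / den^2
    dlogit <- dp * p * (1 - p)
  }
  list(loss = L, dlogit = dlogit)
}

#' Train the skin segmenter on (image, mask) pairs
#'
#' Minimizes pixel-wise binary cross-entropy (or soft Dice) with RMSProp.
#' Deterministic given `seed`.
#'
#' @param model an `"afss_model"` from [build_afss()].
#' @param images list of H x W x C arrays, H and W divisible by 32.
#' @param masks list of H x W binary matrices.
#' @param steps optimizer steps.
#' @param batch_size images per step.
#' @param lr RMSProp learning rate.
#' @param loss `"bce"` or `"dice"`.
#' @param seed integer seed.
#' @return the trained model, with a `history` data frame of losses.
#' @export
train_segmenter <- function(model, images, masks, steps = 500L,
                            batch_size = 8L, lr = 3e-3,
                            loss = c("bce", "dice"), seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(length(images) == length(masks), length(images) >= 1L)
  for (i in seq_along(images)) {
    di <- dim(images[[i]]); dm <- dim(masks[[i]])
    if (!all(di[1:2] == dm[1:2]))
      stop("image/mask size mismatch at pair ", i)
  }
  set.seed(seed)
  opt <- optimizer_new("rmsprop", model$params, lr = lr, weight_decay = 1e-5)
  n <- length(images)
  hist <- numeric(steps)
  for (t in seq_len(steps)) {
    ib <- sample_batch(n, batch_size)
    fm <- images_to_fmap(images[ib])
    tg <- unlist(lapply(masks[ib], as.vector))
    fw <- afss_forward(model, fm, training = TRUE)
    model$buffers <- fw$buffers
    lg <- seg_loss_grad(fw$prob$x[, 1L], tg, loss)
    hist[t] <- lg$loss
    dlog <- fmap(matrix(lg$dlogit, ncol = 1L), fw$prob$H, fw$prob$W,
                 fw$prob$N)
    grads <- afss_backward(model, fw$caches, dlog)
    st <- optimizer_step(opt, model$params, grads)
    model$params <- st$params; opt <- st$opt
  }
  model$history <- if (steps > 0L)
    data.frame(step = seq_len(steps), loss = hist) else
    data.frame(step = integer(), loss = numeric())
  model
}

pad_reflect_to <- function(img, mult = 32L) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  Ht <- as.integer(ceiling(H / mult) * mult)
  Wt <- as.integer(ceiling(W / mult) * mult)
  if (Ht == H && Wt == W) return(list(img = img, H = H, W = W))
  iy <- as.integer(reflect_index(seq_len(Ht), H))
  ix <- as.integer(reflect_index(seq_len(Wt), W))
  list(img = img[iy, ix, , drop = FALSE], H = H, W = W)
}

#' Predicted skin-probability map
#'
#' @param object trained `"afss_model"`.
#' @param newdata one H x W x C array (any size; reflection-padded to a
#'   multiple of 32 internally) or a list of them.
#' @param ... unused.
#' @return matrix (or list of matrices) of skin probabilities in \[0, 1\].
#' @export
predict.afss_model <- function(object, newdata, ...) {
  one <- function(img) {
    pd <- pad_reflect_to(img)
    fm <- images_to_fmap(pd$img)
    fw <- afss_forward(object, fm, training = FALSE)
    pr <- matrix(fw$prob$x[, 1L], fw$prob$H, fw$prob$W)
    pr[seq_len(pd$H), seq_len(pd$W), drop = FALSE]
  }
  if (is.array(newdata) && length(dim(newdata)) == 3L) return(one(newdata))
  lapply(newdata, one)
}

#' Segment an image and mask out non-skin pixels
#'
#' @param model trained `"afss_model"`.
#' @param image H x W x C array in \[0, 1\].
#' @param threshold probability threshold in (0, 1).
#' @return list(mask, prob, image): binary mask, probability map, and the
#'   image with non-skin pixels zeroed.
#' @export
segment_and_crop <- function(model, image, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  prob <- predict(model, image)
  mask <- (prob >= threshold) * 1
  out <- image
  for (ch in seq_len(dim(image)[3L])) out[, , ch] <- image[, , ch] * mask
  list(mask = mask, prob = prob, image = out)
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b binary matrices of equal size.
#' @return scalar IoU; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  inter <- sum(a > 0.5 & b > 0.5)
  un <- sum(a > 0.5 | b > 0.5)
  if (un == 0L) return(1)
  inter / un
}
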