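# Grading classifiers: a pluggable backbone producing an embedding,
# followed by a cosine (AM-Softmax) head. Three desk-scale backbones are
# provided; all expose explicit gradients so the teacher-student feedback
# chain can re-evaluate them at shifted parameter values.
#
#  - "cnn":    3 stride-2 3x3 conv/ReLU stages + global average pool +
#              dropout + linear embedding (default for image experiments)
#  - "mlp":    one hidden ReLU layer on flattened pixels
#  - "linear": embedding is a single linear map (toy/analysis models)

#' Construct a grading classifier
#'
#' @param input_shape integer c(H, W, C) of the expected images, or for the
#'   `"linear"` backbone the input dimension `d`.
#' @param num_classes number of ordinal grades.
#' @param backbone one of `"cnn"`, `"mlp"`, `"linear"`.
#' @param channels conv channel widths per stage (cnn backbone).
#' @param hidden hidden width (mlp backbone).
#' @param embed_dim embedding dimension fed to the cosine head.
#' @param dropout dropout rate applied before the embedding layer during
#'   training.
#' @return object of class `"grader_model"`.
#' @export
grader_model <- function(input_shape, num_classes = 4L,
                         backbone = c("cnn", "mlp", "linear"),
                         channels = c(8L, 16L, 32L), hidden = 64L,
                         embed_dim = 32L, dropout = 0) {
  backbone <- match.arg(backbone)
  params <- list()
  if (backbone == "cnn") {
    stopifnot(length(input_shape) == 3L)
    cin <- input_shape[3L]
    for (i in seq_along(channels)) {
      cout <- channels[i]
      params[[paste0("conv", i, "_W")]] <- he_init(9L * cin, cout, 9L * cin)
      params[[paste0("conv", i, "_b")]] <- numeric(cout)
      cin <- cout
    }
    params$embed_W <- he_init(cin, embed_dim, cin)
    params$embed_b <- numeric(embed_dim)
  } else if (backbone == "mlp") {
    stopifnot(length(input_shape) == 3L)
    din <- prod(input_shape)
    params$fc1_W <- he_init(din, hidden, din)
    params$fc1_b <- numeric(hidden)
    params$embed_W <- he_init(hidden, embed_dim, hidden)
    params$embed_b <- numeric(embed_dim)
  } else {
    din <- if (length(input_shape) == 1L) input_shape else prod(input_shape)
    params$embed_W <- he_init(din, embed_dim, din)
    params$embed_b <- numeric(embed_dim)
  }
  params$head_W <- he_init(embed_dim, num_classes, embed_dim)
  structure(list(backbone = backbone, input_shape = input_shape,
                 num_classes = as.integer(num_classes),
                 channels = channels, hidden = hidden,
                 embed_dim = as.integer(embed_dim), dropout = dropout,
                 params = params),
            class = "grader_model")
}

#' @export
print.grader_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1L)))
  cat(sprintf("<grader_model> backbone=%s classes=%d embed=%d params=%d\n",
              x$backbone, x$num_classes, x$embed_dim, np))
  invisible(x)
}

# input normalisation: images as list of H x W x C arrays, a single array,
# or (linear backbone) a plain numeric matrix n x d.
as_model_input <- function(model, x) {
  if (model$backbone == "linear" && is.matrix(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L) x <- list(x)
  x
}

forward_embed <- function(model, x, training = FALSE) {
  p <- model$params
  caches <- list()
  if (model$backbone == "cnn") {
    fm <- images_to_fmap(x)
    # center pixel intensities so the shared DC component cannot dominate
    # the (cosine-normalized) embedding
    fm$x <- 2 * (fm$x - 0.5)
    for (i in seq_along(model$channels)) {
      cf <- conv_forward(fm, p[[paste0("conv", i, "_W")]],
                         p[[paste0("conv", i, "_b")]], stride = 2L, pad = 1L)
      caches[[paste0("conv", i)]] <- cf$cache
      rf <- relu_forward(cf$out$x)
      caches[[paste0("relu", i)]] <- rf$cache
      fm <- fmap(rf$out, cf$out$H, cf$out$W, cf$out$N)
    }
    gp <- gap_forward(fm)
    caches$gap <- gp$cache
    dp <- dropout_forward(gp$out, model$dropout, training)
    caches$dropout <- dp$cache
    de <- dense_forward(dp$out, p$embed_W, p$embed_b)
    caches$embed <- de$cache
    emb <- de$out
  } else if (model$backbone == "mlp") {
    X <- if (is.matrix(x)) x else
      do.call(rbind, lapply(as_model_input(model, x), as.vector))
    X <- 2 * (X - 0.5)
    d1 <- dense_forward(X, p$fc1_W, p$fc1_b)
    caches$fc1 <- d1$cache
    r1 <- relu_forward(d1$out)
    caches$relu1 <- r1$cache
    dp <- dropout_forward(r1$out, model$dropout, training)
    caches$dropout <- dp$cache
    de <- dense_forward(dp$out, p$embed_W, p$embed_b)
    caches$embed <- de$cache
    emb <- de$out
  } else {
    X <- if (is.matrix(x)) x else
      do.call(rbind, lapply(as_model_input(model, x), as.vector))
    de <- dense_forward(X, p$embed_W, p$embed_b)
    caches$embed <- de$cache
    emb <- de$out
  }
  list(emb = emb, caches = caches)
}

backward_embed <- function(model, caches, demb) {
  p <- model$params
  grads <- list()
  if (model$backbone == "cnn") {
    db <- dense_backward(caches$embed, p$embed_W, demb)
    grads$embed_W <- db$dW; grads$embed_b <- db$db
    dx <- dropout_backward(caches$dropout, db$dinput)
    dfm <- gap_backward(caches$gap, dx)
    for (i in rev(seq_along(model$channels))) {
      dr <- relu_backward(caches[[paste0("relu", i)]], dfm$x)
      dfm$x <- dr
      cb <- conv_backward(caches[[paste0("conv", i)]],
                          p[[paste0("conv", i, "_W")]], dfm)
      grads[[paste0("conv", i, "_W")]] <- cb$dW
      grads[[paste0("conv", i, "_b")]] <- cb$db
      dfm <- cb$dinput
    }
  } else if (model$backbone == "mlp") {
    db <- dense_backward(caches$embed, p$embed_W, demb)
    grads$embed_W <- db$dW; grads$embed_b <- db$db
    dx <- dropout_backward(caches$dropout, db$dinput)
    dx <- relu_backward(caches$relu1, dx)
    d1 <- dense_backward(caches$fc1, p$fc1_W, dx)
    grads$fc1_W <- d1$dW; grads$fc1_b <- d1$db
  } else {
    db <- dense_backward(caches$embed, p$embed_W, demb)
    grads$embed_W <- db$dW; grads$embed_b <- db$db
  }
  grads[names(model$params)[names(model$params) %in% names(grads)]]
}

#' Loss and full parameter gradient for hard labels (AM-Softmax)
#'
#' @param labels integer grades, 0-based.
#' @return list(loss, grads, probs, cos); `grads` has one entry per model
#'   parameter, in the same order as `model$params`.
#' @noRd
model_grad_supervised <- function(model, x, labels, mp, training = FALSE) {
  fe <- forward_embed(model, x, training)
  cos <- cosine_logits(fe$emb, model$params$head_W)
  lab1 <- as.integer(labels) + 1L
  lg <- am_softmax_loss_grad(cos, lab1, mp)
  hb <- cosine_head_backward(fe$emb, model$params$head_W, lg$dcos)
  grads <- backward_embed(model, fe$caches, hb$dF)
  grads$head_W <- hb$dW
  grads <- grads[names(model$params)]
  list(loss = lg$loss, grads = grads, probs = lg$probs, cos = cos)
}

# Soft-target consistency gradient (UDA branch): cross-entropy between a
# fixed target distribution q and the model's softmax over scaled cosines.
model_grad_soft <- function(model, x, target_probs, s, training = FALSE) {
  fe <- forward_embed(model, x, training)
  cos <- cosine_logits(fe$emb, model$params$head_W)
  z <- s * cos
  p <- softmax_rows(z)
  n <- nrow(p)
  loss <- -sum(target_probs * log(pmax(p, 1e-12))) / n
  dcos <- s * (p - target_probs) / n
  hb <- cosine_head_backward(fe$emb, model$params$head_W, dcos)
  grads <- backward_embed(model, fe$caches, hb$dF)
  grads$head_W <- hb$dW
  grads <- grads[names(model$params)]
  list(loss = loss, grads = grads, probs = p)
}

#' Class probabilities of a grading classifier
#'
#' Softmax over scaled cosine logits; no margin is applied at inference.
#' @param temperature optional sharpening temperature (probabilities are
#'   computed from logits divided by it).
#' @noRd
model_probs <- function(model, x, s = 30, temperature = 1) {
  fe <- forward_embed(model, x, FALSE)
  cos <- cosine_logits(fe$emb, model$params$head_W)
  softmax_rows(s * cos / temperature)
}
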