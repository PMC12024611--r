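# Additive-margin softmax (AM-Softmax) over cosine logits.
#
# The classifier head L2-normalizes both the embedding f_i of each sample
# and each class-weight column W_j, so the logit is the cosine
# cos(theta_j) = <f_i, W_j> / (||f_i|| ||W_j||). At training time the
# margin m is subtracted from the target-class cosine only, and all logits
# are scaled by s before the softmax cross-entropy:
#
#   L = -mean_i log[ exp(s (cos_yi - m)) /
#                    (exp(s (cos_yi - m)) + sum_{j != yi} exp(s cos_j)) ]
#
# With m = 0 and s = 1 this reduces to plain softmax cross-entropy on the
# cosines. Optional label smoothing replaces the one-hot target with a
# convex combination of one-hot and uniform before the cross-entropy.

#' Parameters of the additive-margin softmax loss
#'
#' @param s Positive cosine scale. After normalization logits live in
#'   \eqn{[-1, 1]}; the scale restores enough dynamic range for the softmax
#'   to saturate.
#' @param m Additive margin in \eqn{[0, 1)}, subtracted from the
#'   target-class cosine only.
#' @param label_smoothing Smoothing mass in \eqn{[0, 1)} spread uniformly
#'   over classes.
#' @return An object of class `"margin_params"`.
#' @export
margin_params <- function(s = 30, m = 0.35, label_smoothing = 0) {
  stopifnot(is.numeric(s), length(s) == 1L, s > 0)
  stopifnot(is.numeric(m), length(m) == 1L, m >= 0, m < 1)
  stopifnot(is.numeric(label_smoothing), length(label_smoothing) == 1L,
            label_smoothing >= 0, label_smoothing < 1)
  structure(list(s = s, m = m, label_smoothing = label_smoothing),
            class = "margin_params")
}

#' Cosine logits between feature rows and class-weight columns
#'
#' @param features numeric matrix, one embedding per row.
#' @param class_weights numeric matrix `d x classes`, one column per class.
#' @param eps norm guard; a zero-norm row or column with `eps = 0` is a
#'   degenerate input and raises an error.
#' @return matrix `batch x classes` of cosine similarities in \eqn{[-1, 1]}.
#' @export
cosine_logits <- function(features, class_weights, eps = 1e-12) {
  features <- as.matrix(features); class_weights <- as.matrix(class_weights)
  if (ncol(features) != nrow(class_weights))
    stop("feature dimension does not match class_weights rows")
  fn <- sqrt(rowSums(features^2))
  wn <- sqrt(colSums(class_weights^2))
  if (eps <= 0 && (any(fn == 0) || any(wn == 0)))
    stop("zero-norm feature or class weight: degenerate input")
  (features / pmax(fn, eps)) %*% sweep(class_weights, 2L, pmax(wn, eps), "/")
}

#' Apply the additive margin to a target-class cosine
#'
#' @param cos_target cosine value(s) of the target class.
#' @param m additive margin.
#' @return `cos_target - m`.
#' @export
am_margin <- function(cos_target, m) cos_target - m

# Margined, scaled logit matrix: margin applied pre-scaling, target only.
am_logits <- function(cos, labels, params) {
  z <- params$s * cos
  z[cbind(seq_len(nrow(cos)), labels)] <-
    params$s * am_margin(cos[cbind(seq_len(nrow(cos)), labels)], params$m)
  z
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' AM-Softmax loss over cosine logits
#'
#' @param cos matrix of cosine logits (`batch x classes`).
#' @param labels integer class labels in `1..classes`.
#' @param params a [margin_params()] object.
#' @return scalar mean loss with attribute `"probs"` (the margined softmax
#'   probabilities used by the cross-entropy).
#' @export
am_softmax_loss <- function(cos, labels, params = margin_params()) {
  r <- am_softmax_loss_grad(cos, labels, params)
  structure(r$loss, probs = r$probs)
}

#' Loss and gradient with respect to the cosine logits
#'
#' Returns list(loss, dcos, probs); `dcos` is the gradient of the mean loss
#' w.r.t. the unscaled cosines.
#' @noRd
am_softmax_loss_grad <- function(cos, labels, params) {
  n <- nrow(cos); C <- ncol(cos)
  if (any(labels < 1L | labels > C)) stop("label out of range")
  if (any(!is.finite(cos))) stop("non-finite cosine logits")
  z <- am_logits(cos, labels, params)
  zs <- z - apply(z, 1L, max)
  logZ <- log(rowSums(exp(zs)))
  logp <- zs - logZ
  p <- exp(logp)
  ls <- params$label_smoothing
  targ <- matrix(ls / C, n, C)
  targ[cbind(seq_len(n), labels)] <- targ[cbind(seq_len(n), labels)] + (1 - ls)
  loss <- -sum(targ * logp) / n
  dz <- (p - targ) / n
  list(loss = loss, dcos = params$s * dz, probs = p)
}

# Backward through the cosine head: given embeddings F (n x d), weights
# Wc (d x C) and dcos, return gradients w.r.t. F and Wc.
cosine_head_backward <- function(features, class_weights, dcos, eps = 1e-12) {
  fn <- pmax(sqrt(rowSums(features^2)), eps)
  wn <- pmax(sqrt(colSums(class_weights^2)), eps)
  Fn <- features / fn
  Wn <- sweep(class_weights, 2L, wn, "/")
  dFn <- dcos %*% t(Wn)
  dF <- (dFn - Fn * rowSums(dFn * Fn)) / fn
  dWn <- crossprod(Fn, dcos)
  dW <- sweep(dWn - sweep(Wn, 2L, colSums(dWn * Wn), "*"), 2L, wn, "/")
  list(dF = dF, dW = dW)
}
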