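# Optimizers and learning-rate schedules.
#
# Supervised reference runs use Nesterov momentum with cosine decay;
# semi-supervised runs use RMSProp with exponential decay, both after a
# linear warm-up ramp. Weight decay is applied loss-side (L2 added to the
# gradient) with a single coefficient for all parameters.

#' Scale a gradient list so its global L2 norm is at most `max_norm`
#' @noRd
clip_global_norm <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm) || max_norm <= 0) return(grads)
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1L))))
  if (nrm <= max_norm) return(grads)
  lapply(grads, function(g) g * (max_norm / nrm))
}

optimizer_new <- function(kind = c("rmsprop", "nesterov", "sgd"), params,
                          lr = 0.01, momentum = 0.9, rho = 0.9, eps = 1e-8,
                          weight_decay = 0) {
  kind <- match.arg(kind)
  state <- if (kind == "sgd") NULL else param_zero(params)
  list(kind = kind, lr = lr, momentum = momentum, rho = rho, eps = eps,
       weight_decay = weight_decay, state = state)
}

#' One optimizer step. Returns list(params, opt).
#' @noRd
optimizer_step <- function(opt, params, grads, lr_scale = 1) {
  lr <- opt$lr * lr_scale
  if (opt$weight_decay > 0) {
    grads <- mapply(function(g, p) g + opt$weight_decay * p, grads, params,
                    SIMPLIFY = FALSE)
  }
  if (opt$kind == "sgd") {
    params <- mapply(function(p, g) p - lr * g, params, grads, SIMPLIFY = FALSE)
  } else if (opt$kind == "nesterov") {
    opt$state <- mapply(function(v, g) opt$momentum * v + g, opt$state, grads,
                        SIMPLIFY = FALSE)
    params <- mapply(function(p, g, v) p - lr * (g + opt$momentum * v),
                     params, grads, opt$state, SIMPLIFY = FALSE)
  } else { # rmsprop
    opt$state <- mapply(function(v, g) opt$rho * v + (1 - opt$rho) * g^2,
                        opt$state, grads, SIMPLIFY = FALSE)
    params <- mapply(function(p, g, v) p - lr * g / (sqrt(v) + opt$eps),
                     params, grads, opt$state, SIMPLIFY = FALSE)
  }
  list(params = params, opt = opt)
}

#' Learning-rate multiplier at step t (1-based), in [0, 1].
#'
#' Linear warm-up over `warmup` steps, then either cosine decay to zero at
#' `total` steps or exponential decay `rate^((t - warmup) / decay_steps)`.
#' @noRd
lr_schedule <- function(t, warmup, total,
                        kind = c("cosine", "exponential", "constant"),
                        decay_rate = 0.97, decay_steps = 1000) {
  kind <- match.arg(kind)
  if (warmup > 0 && t <= warmup) return(t / warmup)
  if (kind == "constant") return(1)
  if (kind == "cosine") {
    frac <- (t - warmup) / max(1, total - warmup)
    return(0.5 * (1 + cos(pi * min(1, frac))))
  }
  decay_rate^((t - warmup) / decay_steps)
}
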