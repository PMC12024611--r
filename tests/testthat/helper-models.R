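# Shared helpers: tiny deterministic inputs and an independent
# finite-difference gradient oracle.

fd_grad <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# independent plain softmax cross-entropy (mean over rows)
softmax_ce_oracle <- function(logits, labels1) {
  n <- nrow(logits)
  tot <- 0
  for (i in seq_len(n)) {
    z <- logits[i, ]
    tot <- tot - (z[labels1[i]] - log(sum(exp(z))))
  }
  tot / n
}

rand_images <- function(n, H = 16L, W = 16L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) array(runif(H * W * 3), c(H, W, 3)))
}

tiny_fixture_spec <- function() fixture_spec(size = c(32L, 32L))

flatten <- function(p) unlist(p, use.names = FALSE)
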