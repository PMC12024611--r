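# Additive-margin softmax: cosine logit construction, margin arithmetic,
# reduction to plain cross-entropy, and gradient correctness.

test_that("cosine logits match hand-computed similarities and stay bounded", {
  # same direction -> 1, orthogonal -> 0
  f <- matrix(c(1, 0), 1, 2)
  W <- cbind(c(2, 0), c(0, 5))
  cl <- cosine_logits(f, W)
  expect_equal(cl[1, 1], 1)
  expect_equal(cl[1, 2], 0)
  # hand dot-product: f=(3,4), w=(4,3) -> 24/25
  expect_equal(cosine_logits(matrix(c(3, 4), 1), cbind(c(4, 3)))[1, 1], 0.96)
  set.seed(3)
  F <- matrix(rnorm(40), 8, 5)
  W <- matrix(rnorm(20), 5, 4)
  cl <- cosine_logits(F, W)
  expect_true(all(cl >= -1 - 1e-12 & cl <= 1 + 1e-12))
  # degenerate zero-norm feature without the eps guard
  expect_error(cosine_logits(matrix(0, 1, 2), W[1:2, ], eps = 0),
               "degenerate")
})

test_that("the additive margin is plain subtraction on the target cosine", {
  expect_equal(am_margin(0.9, 0.35), 0.55)
  expect_equal(am_margin(0.3, 0), 0.3)
  expect_equal(am_margin(0.0, 0.35), -0.35)
})

test_that("margin parameter validation rejects out-of-range values", {
  expect_error(margin_params(s = -1))
  expect_error(margin_params(m = 1))
  expect_error(margin_params(label_smoothing = 1))
  expect_s3_class(margin_params(), "margin_params")
})

test_that("symmetric two-class cosines give ln 2 and the scalar example matches", {
  cos <- matrix(c(0.4, 0.4), 1, 2)
  expect_equal(as.numeric(am_softmax_loss(cos, 1L, margin_params(1, 0))),
               log(2), tolerance = 1e-12)
  # 2 classes, s = 30, m = 0.35, cos_y = 0.9, cos_other = 0.1:
  # loss = log(1 + exp(30*0.1 - 30*(0.9 - 0.35))) = log1p(exp(-13.5))
  cos <- matrix(c(0.9, 0.1), 1, 2)
  expect_equal(as.numeric(am_softmax_loss(cos, 1L, margin_params(30, 0.35))),
               log1p(exp(-13.5)), tolerance = 1e-10)
})

test_that("with m = 0 and s = 1 the loss reduces to softmax cross-entropy", {
  set.seed(11)
  for (rep in 1:5) {
    cos <- matrix(runif(12, -1, 1), 4, 3)
    y <- sample(1:3, 4, replace = TRUE)
    got <- as.numeric(am_softmax_loss(cos, y, margin_params(1, 0)))
    expect_equal(got, softmax_ce_oracle(cos, y), tolerance = 1e-6)
  }
})

test_that("label smoothing mixes one-hot and uniform targets", {
  cos <- matrix(c(0.8, -0.2, 0.1), 1, 3)
  mp <- margin_params(s = 4, m = 0.1, label_smoothing = 0.3)
  z <- c(4 * (0.8 - 0.1), 4 * -0.2, 4 * 0.1)
  p <- exp(z) / sum(exp(z))
  targ <- c(0.7 + 0.1, 0.1, 0.1)
  expect_equal(as.numeric(am_softmax_loss(cos, 1L, mp)),
               -sum(targ * log(p)), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences through the cosine head", {
  ns <- asNamespace("acnegrader")
  set.seed(42)
  n <- 4; d <- 5; C <- 3
  for (mp in list(margin_params(1, 0), margin_params(12, 0.3, 0.1))) {
    F <- matrix(rnorm(n * d), n, d)
    W <- matrix(rnorm(d * C), d, C)
    y <- sample(1:C, n, replace = TRUE)
    lg <- ns$am_softmax_loss_grad(cosine_logits(F, W), y, mp)
    hb <- ns$cosine_head_backward(F, W, lg$dcos)
    lossF <- function(v) as.numeric(
      am_softmax_loss(cosine_logits(matrix(v, n, d), W), y, mp))
    lossW <- function(v) as.numeric(
      am_softmax_loss(cosine_logits(F, matrix(v, d, C)), y, mp))
    gF <- fd_grad(lossF, as.vector(F))
    gW <- fd_grad(lossW, as.vector(W))
    expect_lt(max(abs(gF - as.vector(hb$dF))) / max(abs(gF)), 1e-4)
    expect_lt(max(abs(gW - as.vector(hb$dW))) / max(abs(gW)), 1e-4)
  }
})

test_that("the loss is monotone in the margin and in the target cosine", {
  set.seed(5)
  cos <- matrix(runif(8, -1, 1), 2, 4)
  y <- c(1L, 3L)
  losses <- vapply(seq(0, 0.9, by = 0.1), function(m)
    as.numeric(am_softmax_loss(cos, y, margin_params(10, m))), numeric(1L))
  expect_true(all(diff(losses) >= -1e-12))
  # larger target cosine, same non-target logits -> strictly smaller loss
  lo <- matrix(c(0.2, 0.1, -0.3), 1, 3)
  hi <- matrix(c(0.7, 0.1, -0.3), 1, 3)
  mp <- margin_params(8, 0.2)
  expect_lt(as.numeric(am_softmax_loss(hi, 1L, mp)),
            as.numeric(am_softmax_loss(lo, 1L, mp)))
})

test_that("non-finite cosines are rejected", {
  expect_error(am_softmax_loss(matrix(c(NaN, 0), 1, 2), 1L, margin_params()),
               "non-finite")
})
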