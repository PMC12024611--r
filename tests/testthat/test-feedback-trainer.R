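# Teacher-student feedback loop: pseudo-label gating, the feedback
# coefficient, the three teacher gradient terms, and the training loop's
# determinism and conservation properties.

test_that("pseudo-labels are confidence-gated with lowest-index tie-break", {
  expect_identical(sample_pseudo_label(c(0.97, 0.01, 0.01, 0.01), 0.95), 0L)
  expect_identical(sample_pseudo_label(rep(0.25, 4), 0.95), NA_integer_)
  expect_identical(sample_pseudo_label(c(0.5, 0.5, 0, 0), 0), 0L)
  expect_error(sample_pseudo_label(c(0.5, 0.2), 0.5), "sum to 1")
  set.seed(1)
  s <- sample_pseudo_label(c(0.5, 0.5, 0, 0), 0, mode = "sample")
  expect_true(s %in% c(0L, 1L))
})

test_that("the feedback coefficient is the scaled gradient inner product", {
  a <- list(w = c(1, 0), b = 0)
  b <- list(w = c(0, 1), b = 5)
  expect_equal(feedback_coefficient(a, b, 0.3), 0)
  u <- list(w = c(0.6, 0.8), b = 0)
  expect_equal(feedback_coefficient(u, u, 0.3), 0.3)
  expect_error(feedback_coefficient(a, list(w = 1, b = 0), 0.1),
               "do not match")
})

test_that("student and teacher updates follow the plain-SGD definition", {
  ns <- asNamespace("acnegrader")
  set.seed(9)
  mdl <- grader_model(3, num_classes = 2, backbone = "linear", embed_dim = 2)
  x <- matrix(rnorm(6), 2, 3)
  y <- c(0L, 1L)
  mp <- margin_params(2, 0.1)
  opt <- ns$optimizer_new("sgd", mdl$params, lr = 0.05)
  su <- student_update(mdl, x, y, mp, opt)
  # oracle: gradient by central finite differences, then theta - lr * g
  f <- function(v) {
    m2 <- mdl; m2$params <- utils::relist(v, mdl$params)
    ns$model_grad_supervised(m2, x, y, mp)$loss
  }
  g_fd <- fd_grad(f, flatten(mdl$params))
  expect_equal(flatten(su$model$params), flatten(mdl$params) - 0.05 * g_fd,
               tolerance = 1e-6)
  # teacher update with all-zero gradients leaves parameters unchanged
  z <- lapply(mdl$params, function(p) p * 0)
  tu <- teacher_update(mdl, z, z, z, ns$optimizer_new("sgd", mdl$params, lr = 1))
  expect_identical(tu$model$params, mdl$params)
  # and with known gradients it is theta - lr * sum
  g1 <- lapply(mdl$params, function(p) p * 0 + 0.1)
  tu <- teacher_update(mdl, g1, g1, g1,
                       ns$optimizer_new("sgd", mdl$params, lr = 0.2))
  expect_equal(flatten(tu$model$params), flatten(mdl$params) - 0.2 * 0.3,
               tolerance = 1e-12)
})

test_that("the feedback teacher gradient scales linearly in h and vanishes at 0", {
  set.seed(10)
  mdl <- grader_model(3, num_classes = 2, backbone = "linear", embed_dim = 2)
  x <- matrix(rnorm(3), 1, 3)
  mp <- margin_params(2, 0.1)
  g0 <- teacher_feedback_gradient(mdl, x, 0L, 0, mp)
  expect_true(all(abs(flatten(g0$grads)) == 0))
  g1 <- teacher_feedback_gradient(mdl, x, 0L, 1, mp)
  g2 <- teacher_feedback_gradient(mdl, x, 0L, 2, mp)
  expect_equal(flatten(g2$grads), 2 * flatten(g1$grads), tolerance = 1e-12)
})

test_that("the consistency gradient vanishes for matched distributions", {
  set.seed(12)
  mdl <- grader_model(3, num_classes = 2, backbone = "linear", embed_dim = 2)
  x <- matrix(rnorm(6), 2, 3)
  # no augmentation and no sharpening: target equals prediction
  g <- uda_gradient(mdl, x, policy = NULL, temperature = 1, uda_factor = 1,
                    s = 5)
  expect_lt(max(abs(flatten(g$grads))), 1e-10)
  g0 <- uda_gradient(mdl, x, policy = NULL, temperature = 0.8,
                     uda_factor = 0, s = 5)
  expect_true(all(flatten(g0$grads) == 0))
})

test_that("hand-set two-class consistency gradient matches the scalar oracle", {
  ns <- asNamespace("acnegrader")
  set.seed(13)
  mdl <- grader_model(2, num_classes = 2, backbone = "linear", embed_dim = 2)
  x <- matrix(rnorm(2), 1, 2)
  s <- 3; temp <- 0.7
  q <- ns$model_probs(mdl, x, s = s, temperature = temp)
  f <- function(v) {
    m2 <- mdl; m2$params <- utils::relist(v, mdl$params)
    p <- ns$model_probs(m2, x, s = s)
    -sum(q * log(p))
  }
  g_fd <- fd_grad(f, flatten(mdl$params))
  g <- uda_gradient(mdl, x, policy = NULL, temperature = temp,
                    uda_factor = 1, s = s)
  expect_equal(flatten(g$grads), g_fd, tolerance = 1e-5)
})

test_that("the h-chain teacher gradient matches the unrolled objective to first order", {
  # <= 10-parameter toy: linear teacher/student, 2 features, 2 classes.
  # Expectation over the pseudo-label draw (REINFORCE identity) vs central
  # finite differences of L_l(theta_S - eta_s * grad L_u(theta_T, theta_S)).
  ns <- asNamespace("acnegrader")
  set.seed(7)
  d <- 2; C <- 2
  mk <- function() grader_model(d, num_classes = C, backbone = "linear",
                                embed_dim = 2)
  teacher <- mk(); student <- mk()
  mp <- margin_params(1, 0)
  xu <- matrix(rnorm(d), 1, d)
  xl <- matrix(rnorm(2 * d), 2, d); yl <- c(0L, 1L)
  eta_s <- 1e-5
  gsup <- function(m, x, y) ns$model_grad_supervised(m, x, y, mp)$grads
  pT <- ns$model_probs(teacher, xu, s = 1)
  gT <- ns$param_zero(teacher$params)
  for (cl in 0:(C - 1)) {
    gu <- gsup(student, xu, cl)
    s2 <- student
    s2$params <- ns$param_axpy(student$params, gu, -eta_s)
    h <- feedback_coefficient(gsup(s2, xl, yl), gu, eta_s)
    gt <- teacher_feedback_gradient(teacher, xu, cl, h, mp)$grads
    gT <- mapply(function(a, b) a + pT[1, cl + 1] * b, gT, gt,
                 SIMPLIFY = FALSE)
  }
  phi <- function(tv) {
    t2 <- teacher; t2$params <- utils::relist(tv, teacher$params)
    pT2 <- ns$model_probs(t2, xu, s = 1)
    gu_soft <- ns$param_zero(student$params)
    for (cl in 0:(C - 1)) {
      gu <- gsup(student, xu, cl)
      gu_soft <- mapply(function(a, b) a + pT2[1, cl + 1] * b, gu_soft, gu,
                        SIMPLIFY = FALSE)
    }
    s2 <- student
    s2$params <- ns$param_axpy(student$params, gu_soft, -eta_s)
    ns$model_grad_supervised(s2, xl, yl, mp)$loss
  }
  g_fd <- fd_grad(phi, flatten(teacher$params), h = 1e-4)
  relerr <- sqrt(sum((g_fd - flatten(gT))^2)) / sqrt(sum(g_fd^2))
  expect_lt(relerr, 1e-3)
})

test_that("the training loop is deterministic, conservative and returns the student", {
  spec <- tiny_fixture_spec()
  set.seed(77)
  mini <- function(seed) {
    ds <- gen_graded_dataset(spec, n_per_grade = 4, labeled_fraction = 0.5,
                             n_heldout_per_grade = 0, seed = 50)
    cfg <- aff_config(semi_supervised = list(steps = 6L, warmup = 2L,
        lr_student = 0.01, lr_teacher = 0.01, dropout_student = 0,
        dropout_teacher = 0), seed = seed)
    aff_train(ds$labeled, ds$unlabeled$images, cfg)
  }
  f1 <- mini(3); f2 <- mini(3)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$student$params, f2$student$params)
  expect_s3_class(f1, "aff_fit")
  expect_true(all(f1$history$keep_fraction >= 0 &
                  f1$history$keep_fraction <= 1))
  expect_true(all(is.finite(f1$history$h)))

  # 0 steps: the initial student comes back untouched
  ds <- gen_graded_dataset(spec, n_per_grade = 2, labeled_fraction = 0.5,
                           n_heldout_per_grade = 0, seed = 51)
  cfg0 <- aff_config(semi_supervised = list(steps = 0L), seed = 1)
  f0 <- aff_train(ds$labeled, ds$unlabeled$images, cfg0)
  expect_identical(nrow(f0$history), 0L)

  # teacher conservation at zero teacher learning rate
  recorded <- list()
  factory <- function(dropout = 0) {
    m <- grader_model(c(32L, 32L, 3L), num_classes = 4, backbone = "cnn",
                      channels = c(2L, 3L), embed_dim = 4)
    recorded[[length(recorded) + 1L]] <<- m
    m
  }
  cfg <- aff_config(semi_supervised = list(steps = 4L, warmup = 1L,
      lr_student = 0.01, lr_teacher = 0, dropout_student = 0,
      dropout_teacher = 0), seed = 5)
  ds2 <- gen_graded_dataset(spec, n_per_grade = 3, labeled_fraction = 0.5,
                            n_heldout_per_grade = 0, seed = 52)
  fz <- aff_train(ds2$labeled, ds2$unlabeled$images, cfg,
                  backbone_factory = factory)
  expect_equal(fz$teacher$params, recorded[[1L]]$params, tolerance = 1e-14)
})

test_that("disabling feedback reduces to one-way pseudo-labeling (h unused)", {
  spec <- tiny_fixture_spec()
  ds <- gen_graded_dataset(spec, n_per_grade = 4, labeled_fraction = 0.5,
                           n_heldout_per_grade = 0, seed = 53)
  cfg <- aff_config(semi_supervised = list(steps = 6L, warmup = 2L,
      lr_student = 0.02, lr_teacher = 0.02, dropout_student = 0,
      dropout_teacher = 0, feedback = FALSE, pseudo_threshold = 0.25),
      seed = 2)
  f <- aff_train(ds$labeled, ds$unlabeled$images, cfg)
  expect_true(all(f$history$h == 0))
  expect_gt(mean(f$history$keep_fraction), 0)
})

test_that("prediction methods agree between the fit object and its student", {
  spec <- tiny_fixture_spec()
  ds <- gen_graded_dataset(spec, n_per_grade = 3, labeled_fraction = 0.5,
                           n_heldout_per_grade = 2, seed = 54)
  cfg <- aff_config(semi_supervised = list(steps = 3L, warmup = 1L,
      dropout_student = 0, dropout_teacher = 0, lr_student = 0.01,
      lr_teacher = 0.01), seed = 4)
  f <- aff_train(ds$labeled, ds$unlabeled$images, cfg)
  p1 <- predict(f, ds$heldout$images)
  p2 <- predict(f$student, ds$heldout$images, s = f$config$loss$s)
  expect_identical(p1, p2)
  pr <- predict(f, ds$heldout$images, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-9)
  expect_type(coef(f), "double")
  expect_output(print(summary(f)), "Feedback pseudo-label")
})
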