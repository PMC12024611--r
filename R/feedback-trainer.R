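# Feedback pseudo-label training (AFF).
#
# A teacher network pseudo-labels unlabeled images for a student; the
# student takes one optimizer step on those pseudo-labels only. The
# student's subsequent performance on *labeled* data is condensed into a
# scalar feedback coefficient
#
#   h = eta_s * < grad_labeled(theta_S^{t+1}), grad_unlabeled(theta_S^t) >
#
# which scales the teacher's own gradient on the pseudo-labeled batch, so
# pseudo-labels that helped the student (positive alignment of the two
# gradients) are reinforced and harmful ones are penalized. The teacher
# additionally receives a plain supervised gradient on the labeled batch
# and an augmentation-consistency (UDA) gradient, and is updated on the
# sum of the three. The student, never the teacher, is the returned model.

#' Training configuration with literature defaults
#'
#' Defaults mirror the reference hyperparameter tables: supervised runs use
#' Nesterov momentum 0.9 with cosine decay from 0.01; semi-supervised runs
#' use RMSProp with exponential decay, student/teacher learning rates
#' 0.3/0.125, batch sizes 8/8, dropout 0.35/0.5, UDA factor 1.0, UDA
#' temperature 0.8, pseudo-label threshold 0.95, weight decay 5e-4,
#' batch-norm decay 0.99 and label smoothing 0.1. Any entry can be
#' overridden through `...` using nested lists.
#'
#' @param ... named overrides, e.g. `semi_supervised = list(steps = 500)`.
#' @return nested list of class `"aff_config"`.
#' @export
aff_config <- function(...) {
  cfg <- list(
    supervised = list(
      lr = 0.01, momentum = 0.9, schedule = "cosine",
      steps = 50000L, warmup = 2500L, batch_size = 16L,
      dropout = 0.2, weight_decay = 5e-4, bn_decay = 0.99
    ),
    semi_supervised = list(
      steps = 3000000L, warmup = 2000L,
      lr_student = 0.3, lr_teacher = 0.125,
      batch_labeled = 8L, batch_unlabeled = 8L,
      dropout_student = 0.35, dropout_teacher = 0.5,
      uda_factor = 1.0, uda_temperature = 0.8,
      pseudo_threshold = 0.95, pseudo_mode = "argmax",
      uda_on = "unlabeled", feedback = TRUE,
      weight_decay = 5e-4, bn_decay = 0.99, label_smoothing = 0.1,
      decay_rate = 0.97, decay_steps = 1000L, grad_clip = 1.0
    ),
    loss = list(s = 30, m = 0.35, label_smoothing = 0.1),
    augment = list(preset = "aa", n_ops = 2L, magnitude = 9L),
    seed = 1L
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && nm %in% names(cfg)) {
      for (k in names(ov[[nm]])) cfg[[nm]][[k]] <- ov[[nm]][[k]]
    } else cfg[[nm]] <- ov[[nm]]
  }
  structure(cfg, class = "aff_config")
}

#' Pseudo-label from a teacher probability vector
#'
#' Accepts the prediction only if the maximum probability reaches
#' `threshold`; otherwise the sample is rejected (returns `NA`).
#' `mode = "argmax"` takes the most probable class (ties broken toward the
#' lowest index); `mode = "sample"` draws from the categorical
#' distribution, then applies the same confidence gate.
#'
#' @param probs nonnegative vector summing to 1 (tolerance 1e-6).
#' @param threshold confidence threshold in (0, 1].
#' @param mode `"argmax"` or `"sample"`.
#' @return 0-based class index, or `NA_integer_` if rejected.
#' @export
sample_pseudo_label <- function(probs, threshold = 0.95,
                                mode = c("argmax", "sample")) {
  mode <- match.arg(mode)
  if (any(probs < -1e-12) || abs(sum(probs) - 1) > 1e-6)
    stop("probs must be nonnegative and sum to 1")
  if (max(probs) < threshold) return(NA_integer_)
  if (mode == "argmax") return(which.max(probs) - 1L)
  as.integer(sample.int(length(probs), 1L, prob = probs) - 1L)
}

pseudo_label_batch <- function(probmat, threshold, mode) {
  apply(probmat, 1L, sample_pseudo_label, threshold = threshold, mode = mode)
}

#' Scalar feedback coefficient
#'
#' Inner product, across all parameters, of the student's labeled-loss
#' gradient after its update with its pseudo-label-loss gradient before it,
#' scaled by the student step size actually taken.
#'
#' @param g_l_after,g_u_before parameter-gradient lists with identical
#'   structure.
#' @param eta_s the student learning rate used for the update.
#' @return scalar `h`.
#' @export
feedback_coefficient <- function(g_l_after, g_u_before, eta_s) {
  if (!identical(names(g_l_after), names(g_u_before)) ||
      !all(mapply(function(a, b) length(a) == length(b),
                  g_l_after, g_u_before)))
    stop("gradient structures do not match")
  eta_s * param_dot(g_l_after, g_u_before)
}

#' One student step on pseudo-labeled data
#'
#' @param student a [grader_model()].
#' @param x_u accepted unlabeled images.
#' @param y_u_hat their 0-based pseudo-labels.
#' @param mp [margin_params()].
#' @param opt student optimizer state.
#' @param lr_scale schedule multiplier for this step.
#' @return list(model, opt, g_u, loss).
#' @export
student_update <- function(student, x_u, y_u_hat, mp, opt, lr_scale = 1,
                           training = TRUE, grad_clip = NULL) {
  r <- model_grad_supervised(student, x_u, y_u_hat, mp, training = training)
  st <- optimizer_step(opt, student$params, clip_global_norm(r$grads, grad_clip),
                       lr_scale)
  student$params <- st$params
  list(model = student, opt = st$opt, g_u = r$grads, loss = r$loss)
}

#' Teacher gradient induced by student feedback
#'
#' `h` times the teacher's AM-Softmax gradient on the same pseudo-labeled
#' batch the student trained on.
#' @export
teacher_feedback_gradient <- function(teacher, x_u, y_u_hat, h, mp,
                                      training = TRUE) {
  r <- model_grad_supervised(teacher, x_u, y_u_hat, mp, training = training)
  list(grads = lapply(r$grads, function(g) h * g), loss = r$loss)
}

#' Augmentation-consistency (UDA) gradient for the teacher
#'
#' Cross-entropy between the temperature-sharpened, gradient-blocked
#' teacher prediction on the clean images and the teacher prediction on
#' their augmented views; only the augmented branch contributes gradient.
#'
#' @param x list of images.
#' @param policy an [aa_policy()]; `NULL` disables augmentation (views are
#'   the clean images).
#' @param temperature sharpening temperature for the target branch.
#' @param uda_factor multiplier on the returned gradient.
#' @export
uda_gradient <- function(teacher, x, policy, temperature, uda_factor, s,
                         training = TRUE) {
  stopifnot(temperature > 0)
  if (uda_factor == 0) {
    return(list(grads = param_zero(teacher$params), loss = 0))
  }
  q <- model_probs(teacher, x, s = s, temperature = temperature)
  views <- if (is.null(policy)) x else lapply(x, aa_apply, policy = policy)
  r <- model_grad_soft(teacher, views, q, s, training = training)
  list(grads = lapply(r$grads, function(g) uda_factor * g), loss = r$loss)
}

#' One teacher step on the sum of the three gradient terms
#' @export
teacher_update <- function(teacher, g_feedback, g_supervised, g_uda, opt,
                           lr_scale = 1, grad_clip = NULL) {
  g <- mapply(function(a, b, c) a + b + c, g_feedback, g_supervised, g_uda,
              SIMPLIFY = FALSE)
  st <- optimizer_step(opt, teacher$params, clip_global_norm(g, grad_clip),
                       lr_scale)
  teacher$params <- st$params
  list(model = teacher, opt = st$opt)
}

sample_batch <- function(n, size) {
  if (n <= size) seq_len(n) else sample.int(n, size)
}

#' Train an acne grader with feedback pseudo-label learning
#'
#' Runs the full alternating teacher-student loop and returns the trained
#' *student* (the teacher is kept alongside for inspection). Deterministic
#' given `config$seed`.
#'
#' @param labeled list with elements `images` (list of H x W x C arrays in
#'   \[0, 1\]) and `labels` (integer grades, 0-based).
#' @param unlabeled list of images.
#' @param config an [aff_config()]; `config$semi_supervised$steps` controls
#'   the loop length.
#' @param backbone_factory function returning a fresh [grader_model()];
#'   called twice (teacher, student). Defaults to the small CNN backbone
#'   sized from the first labeled image.
#' @param eval_data optional list(images, labels) evaluated every
#'   `eval_every` steps into the history.
#' @param eval_every evaluation cadence in steps.
#' @return object of class `"aff_fit"` with the student model, teacher
#'   model, per-step history data frame and the config.
#' @export
aff_train <- function(labeled, unlabeled, config = aff_config(),
                      backbone_factory = NULL, eval_data = NULL,
                      eval_every = 100L) {
  stopifnot(length(labeled$images) >= 1L, length(unlabeled) >= 1L)
  if (length(unique(labeled$labels)) < 2L)
    stop("need at least 2 classes in the labeled set")
  ss <- config$semi_supervised
  mp <- margin_params(config$loss$s, config$loss$m,
                      config$loss$label_smoothing)
  mp_nosmooth <- margin_params(config$loss$s, config$loss$m, 0)
  set.seed(config$seed)
  if (is.null(backbone_factory)) {
    shp <- dim(labeled$images[[1L]])
    backbone_factory <- function(dropout = 0) {
      grader_model(shp, num_classes = max(labeled$labels) + 1L,
                   backbone = "cnn", dropout = dropout)
    }
  }
  teacher <- backbone_factory(ss$dropout_teacher)
  student <- backbone_factory(ss$dropout_student)
  policy <- if (config$augment$n_ops > 0L)
    aa_policy(preset = config$augment$preset, n_ops = config$augment$n_ops,
              magnitude = config$augment$magnitude) else NULL
  opt_t <- optimizer_new("rmsprop", teacher$params, lr = ss$lr_teacher,
                         weight_decay = ss$weight_decay)
  opt_s <- optimizer_new("rmsprop", student$params, lr = ss$lr_student,
                         weight_decay = ss$weight_decay)
  nl <- length(labeled$images); nu <- length(unlabeled)
  steps <- as.integer(ss$steps)
  hist <- vector("list", steps)
  for (t in seq_len(steps)) {
    sc <- lr_schedule(t, ss$warmup, steps, "exponential",
                      ss$decay_rate, ss$decay_steps)
    il <- sample_batch(nl, ss$batch_labeled)
    iu <- sample_batch(nu, ss$batch_unlabeled)
    xl <- labeled$images[il]; yl <- labeled$labels[il]
    xu <- unlabeled[iu]
    # teacher pseudo-labels (hard, confidence-gated)
    tp <- model_probs(teacher, xu, s = config$loss$s)
    yu <- pseudo_label_batch(tp, ss$pseudo_threshold, ss$pseudo_mode)
    acc <- which(!is.na(yu))
    keep <- length(acc) / length(yu)
    h <- 0; loss_u <- NA_real_
    g_fb <- param_zero(teacher$params)
    if (length(acc) > 0L) {
      # pseudo-labels are assigned on the clean view; the student then
      # trains on an augmented (noised) view of the same images, the
      # noisy-student recipe that makes pseudo-labeling regularize rather
      # than self-confirm
      xua <- if (is.null(policy)) xu[acc] else
        lapply(xu[acc], aa_apply, policy = policy)
      su <- student_update(student, xua, yu[acc], mp_nosmooth, opt_s, sc,
                           grad_clip = ss$grad_clip)
      student <- su$model; opt_s <- su$opt; loss_u <- su$loss
      if (isTRUE(ss$feedback)) {
        # with feedback disabled the loop degenerates to one-way
        # pseudo-labeling: h stays 0 and is never used
        gl <- model_grad_supervised(student, xl, yl, mp_nosmooth,
                                    training = TRUE)
        h <- feedback_coefficient(gl$grads, su$g_u, ss$lr_student * sc)
        fb <- teacher_feedback_gradient(teacher, xua, yu[acc], h, mp)
        g_fb <- fb$grads
      }
    }
    xls <- if (is.null(policy)) xl else lapply(xl, aa_apply, policy = policy)
    gs <- model_grad_supervised(teacher, xls, yl, mp, training = TRUE)
    x_uda <- if (identical(ss$uda_on, "labeled")) xl else xu
    gu <- uda_gradient(teacher, x_uda, policy, ss$uda_temperature,
                       ss$uda_factor, config$loss$s)
    tu <- teacher_update(teacher, g_fb, gs$grads, gu$grads, opt_t, sc,
                         grad_clip = ss$grad_clip)
    teacher <- tu$model; opt_t <- tu$opt
    if (t %% 50L == 0L) {
      stopifnot_finite(teacher$params, "teacher parameters")
      stopifnot_finite(student$params, "student parameters")
    }
    ev <- NA_real_
    if (!is.null(eval_data) && (t %% eval_every == 0L || t == steps)) {
      pr <- predict(student, eval_data$images, s = config$loss$s)
      ev <- mean(pr == eval_data$labels)
    }
    hist[[t]] <- data.frame(step = t, h = h, keep_fraction = keep,
                            loss_student_unlabeled = loss_u,
                            loss_teacher_supervised = gs$loss,
                            loss_teacher_uda = gu$loss,
                            lr_scale = sc, eval_accuracy = ev)
  }
  history <- if (steps > 0L) do.call(rbind, hist) else
    data.frame(step = integer(), h = numeric(), keep_fraction = numeric(),
               loss_student_unlabeled = numeric(),
               loss_teacher_supervised = numeric(),
               loss_teacher_uda = numeric(), lr_scale = numeric(),
               eval_accuracy = numeric())
  structure(list(student = student, teacher = teacher, history = history,
                 config = config),
            class = "aff_fit")
}

#' Supervised reference training (Nesterov momentum + cosine decay)
#'
#' Trains a single model on labeled data only, with the same augmentation
#' policy applied to training batches; this is the baseline the
#' semi-supervised framework is compared against.
#'
#' @inheritParams aff_train
#' @param augment logical; apply the configured augmentation policy to the
#'   training batches.
#' @return object of class `"supervised_fit"`.
#' @export
supervised_train <- function(labeled, config = aff_config(),
                             backbone_factory = NULL, augment = TRUE,
                             eval_data = NULL, eval_every = 100L) {
  sv <- config$supervised
  mp <- margin_params(config$loss$s, config$loss$m,
                      config$loss$label_smoothing)
  set.seed(config$seed)
  if (is.null(backbone_factory)) {
    shp <- dim(labeled$images[[1L]])
    backbone_factory <- function(dropout = 0) {
      grader_model(shp, num_classes = max(labeled$labels) + 1L,
                   backbone = "cnn", dropout = dropout)
    }
  }
  model <- backbone_factory(sv$dropout)
  policy <- if (augment)
    aa_policy(preset = config$augment$preset, n_ops = config$augment$n_ops,
              magnitude = config$augment$magnitude) else NULL
  opt <- optimizer_new("nesterov", model$params, lr = sv$lr,
                       momentum = sv$momentum, weight_decay = sv$weight_decay)
  n <- length(labeled$images)
  steps <- as.integer(sv$steps)
  hist <- vector("list", steps)
  for (t in seq_len(steps)) {
    sc <- lr_schedule(t, sv$warmup, steps, "cosine")
    ib <- sample_batch(n, sv$batch_size)
    xb <- labeled$images[ib]
    if (!is.null(policy)) xb <- lapply(xb, aa_apply, policy = policy)
    r <- model_grad_supervised(model, xb, labeled$labels[ib], mp,
                               training = TRUE)
    st <- optimizer_step(opt, model$params, r$grads, sc)
    model$params <- st$params; opt <- st$opt
    ev <- NA_real_
    if (!is.null(eval_data) && (t %% eval_every == 0L || t == steps)) {
      pr <- predict(model, eval_data$images, s = config$loss$s)
      ev <- mean(pr == eval_data$labels)
    }
    hist[[t]] <- data.frame(step = t, loss = r$loss, lr_scale = sc,
                            eval_accuracy = ev)
  }
  history <- if (steps > 0L) do.call(rbind, hist) else
    data.frame(step = integer(), loss = numeric(), lr_scale = numeric(),
               eval_accuracy = numeric())
  structure(list(model = model, history = history, config = config),
            class = "supervised_fit")
}

# ---- S3 methods ----------------------------------------------------------

#' Predict grades for new images
#'
#' @param object a fitted model.
#' @param newdata list of images (H x W x C arrays).
#' @param type `"class"` for 0-based grades, `"prob"` for the probability
#'   matrix.
#' @param s cosine scale used for the softmax.
#' @param ... unused.
#' @export
predict.grader_model <- function(object, newdata, type = c("class", "prob"),
                                 s = 30, ...) {
  type <- match.arg(type)
  p <- model_probs(object, newdata, s = s)
  if (type == "prob") return(p)
  as.integer(max.col(p, ties.method = "first") - 1L)
}

#' @rdname predict.grader_model
#' @export
predict.aff_fit <- function(object, newdata, type = c("class", "prob"),
                            s = NULL, ...) {
  if (is.null(s)) s <- object$config$loss$s
  predict(object$student, newdata, type = type, s = s, ...)
}

#' @rdname predict.grader_model
#' @export
predict.supervised_fit <- function(object, newdata,
                                   type = c("class", "prob"), s = NULL, ...) {
  if (is.null(s)) s <- object$config$loss$s
  predict(object$model, newdata, type = type, s = s, ...)
}

#' @export
print.aff_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("Feedback pseudo-label fit: %d steps\n", n))
  if (n > 0L) {
    cat(sprintf("  final keep fraction: %.2f   mean |h|: %.3g\n",
                x$history$keep_fraction[n],
                mean(abs(x$history$h), na.rm = TRUE)))
    ev <- x$history$eval_accuracy
    if (any(!is.na(ev)))
      cat(sprintf("  last held-out accuracy: %.3f\n", ev[max(which(!is.na(ev)))]))
  }
  invisible(x)
}

#' @export
summary.aff_fit <- function(object, ...) {
  h <- object$history
  out <- list(
    steps = nrow(h),
    keep_fraction_mean = mean(h$keep_fraction),
    h_mean = mean(h$h), h_sd = stats::sd(h$h),
    final_supervised_loss = utils::tail(h$loss_teacher_supervised, 1L),
    final_uda_loss = utils::tail(h$loss_teacher_uda, 1L)
  )
  class(out) <- "summary.aff_fit"
  out
}

#' @export
print.summary.aff_fit <- function(x, ...) {
  cat(sprintf(
    "Feedback pseudo-label training over %d steps\n  mean keep fraction %.3f\n  feedback h: mean %.4g (sd %.4g)\n  final teacher losses: supervised %.4g, consistency %.4g\n",
    x$steps, x$keep_fraction_mean, x$h_mean, x$h_sd,
    x$final_supervised_loss, x$final_uda_loss))
  invisible(x)
}

#' @export
coef.aff_fit <- function(object, ...) flatten_params(object$student$params)

#' @export
plot.aff_fit <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  graphics::plot(h$step, h$keep_fraction, type = "l", xlab = "step",
                 ylab = "pseudo-label keep fraction", ylim = c(0, 1), ...)
  graphics::plot(h$step, h$h, type = "l", xlab = "step",
                 ylab = "feedback coefficient h", ...)
  invisible(x)
}

#' @export
print.supervised_fit <- function(x, ...) {
  cat(sprintf("Supervised reference fit: %d steps\n", nrow(x$history)))
  invisible(x)
}
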