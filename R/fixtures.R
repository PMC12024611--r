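# Synthetic graded-face fixtures.
#
# Each image is a skin-toned ellipse ("face") on a noisy background, with
# a grade-dependent number of reddish lesion blobs rendered on skin only,
# an optional gray occluder rectangle (mask/clutter negative), global
# brightness jitter and per-image skin-tone jitter. The matching skin mask
# marks the visible skin ellipse (occluded pixels are not skin). Grades
# 0-3 map to disjoint, increasing lesion-count intervals, so grade
# evidence is lesion density -- a chromatic signal that brightness or
# equalization augmentation does not destroy, while exact counts near the
# interval boundaries keep the task genuinely noisy.

#' Fixture generation settings
#'
#' @param size c(H, W) of the images.
#' @param grade_lesion_ranges list of 4 count intervals c(lo, hi), one per
#'   grade, disjoint and increasing.
#' @param skin_tone mean skin RGB.
#' @param skin_jitter per-image uniform jitter half-width on the skin RGB.
#' @param background_level mean background gray level.
#' @param noise_sd pixel noise standard deviation.
#' @param brightness_jitter half-width of the global brightness factor
#'   jitter around 1.
#' @param occluder_prob probability that an image carries a gray occluder
#'   rectangle.
#' @return list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(size = c(64L, 64L),
                         grade_lesion_ranges = list(c(0L, 2L), c(3L, 10L),
                                                    c(11L, 25L), c(26L, 60L)),
                         skin_tone = c(0.80, 0.62, 0.50),
                         skin_jitter = 0.06,
                         background_level = 0.35,
                         noise_sd = 0.03,
                         brightness_jitter = 0.12,
                         occluder_prob = 0.3) {
  lo <- vapply(grade_lesion_ranges, `[`, numeric(1L), 1L)
  hi <- vapply(grade_lesion_ranges, `[`, numeric(1L), 2L)
  if (any(lo > hi) || any(diff(lo) <= 0) || any(hi[-length(hi)] >= lo[-1L]))
    stop("grade_lesion_ranges must be disjoint and increasing")
  structure(list(size = as.integer(size),
                 grade_lesion_ranges = grade_lesion_ranges,
                 skin_tone = skin_tone, skin_jitter = skin_jitter,
                 background_level = background_level, noise_sd = noise_sd,
                 brightness_jitter = brightness_jitter,
                 occluder_prob = occluder_prob),
            class = "fixture_spec")
}

#' Render one synthetic graded face image
#'
#' @param spec a [fixture_spec()].
#' @param grade integer grade in 0..3.
#' @param seed optional seed for a self-contained deterministic call.
#' @return list(image, mask, grade, lesion_count).
#' @export
gen_face_image <- function(spec = fixture_spec(), grade, seed = NULL) {
  stopifnot(grade %in% 0:3)
  if (!is.null(seed)) set.seed(seed)
  H <- spec$size[1L]; W <- spec$size[2L]
  img <- array(stats::rnorm(H * W * 3, spec$background_level, spec$noise_sd),
               c(H, W, 3))
  # skin ellipse
  cy <- H / 2 + stats::runif(1, -H / 16, H / 16)
  cx <- W / 2 + stats::runif(1, -W / 16, W / 16)
  ry <- stats::runif(1, 0.30, 0.42) * H
  rx <- stats::runif(1, 0.26, 0.38) * W
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  ellipse <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
  tone <- spec$skin_tone + stats::runif(3, -spec$skin_jitter, spec$skin_jitter)
  for (ch in 1:3) {
    M <- img[, , ch]
    M[ellipse] <- tone[ch] + stats::rnorm(sum(ellipse), 0, spec$noise_sd / 2)
    img[, , ch] <- M
  }
  # lesions: reddish gaussian blobs on skin
  rng <- spec$grade_lesion_ranges[[grade + 1L]]
  count <- if (rng[1L] == rng[2L]) rng[1L] else
    sample(seq.int(rng[1L], rng[2L]), 1L)
  inside <- which(ellipse)
  for (l in seq_len(count)) {
    p <- inside[sample.int(length(inside), 1L)]
    ly <- (p - 1L) %% H + 1L
    lx <- (p - 1L) %/% H + 1L
    rad <- stats::runif(1, 2, 6) * min(H, W) / 64
    amp <- stats::runif(1, 0.25, 0.40)
    span <- ceiling(2 * rad)
    ys <- max(1L, ly - span):min(H, ly + span)
    xs <- max(1L, lx - span):min(W, lx + span)
    d2 <- outer((ys - ly)^2, (xs - lx)^2, "+")
    g <- amp * exp(-d2 / (2 * (rad / 2)^2))
    onskin <- ellipse[ys, xs, drop = FALSE]
    img[ys, xs, 1L] <- img[ys, xs, 1L] + g * 0.9 * onskin
    img[ys, xs, 2L] <- img[ys, xs, 2L] - g * 0.55 * onskin
    img[ys, xs, 3L] <- img[ys, xs, 3L] - 0.45 * g * onskin
  }
  mask <- ellipse * 1
  # occluder rectangle (non-skin clutter, may cover skin)
  if (stats::runif(1) < spec$occluder_prob) {
    oh <- sample.int(max(2L, H %/% 4), 1L) + H %/% 8
    ow <- sample.int(max(2L, W %/% 4), 1L) + W %/% 8
    oy <- sample.int(max(1L, H - oh), 1L)
    ox <- sample.int(max(1L, W - ow), 1L)
    lev <- stats::runif(1, 0.45, 0.7)
    for (ch in 1:3)
      img[oy:(oy + oh - 1L), ox:(ox + ow - 1L), ch] <-
        lev + stats::rnorm(oh * ow, 0, spec$noise_sd / 2)
    mask[oy:(oy + oh - 1L), ox:(ox + ow - 1L)] <- 0
  }
  img <- img * stats::runif(1, 1 - spec$brightness_jitter,
                            1 + spec$brightness_jitter)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask, grade = as.integer(grade),
       lesion_count = as.integer(count))
}

#' Generate a stratified graded dataset with labeled/unlabeled/held-out splits
#'
#' @param spec a [fixture_spec()].
#' @param n_per_grade training-pool images per grade.
#' @param labeled_fraction fraction of the training pool kept labeled
#'   (stratified per grade); the rest becomes the unlabeled pool.
#' @param n_heldout_per_grade held-out evaluation images per grade.
#' @param seed integer seed; the whole dataset is a pure function of it.
#' @return list with `labeled` (images, labels, names), `unlabeled`
#'   (images, names; true labels kept separately as `unlabeled_truth` for
#'   diagnostics only), `heldout` (images, labels, names), `masks` (skin
#'   masks of the labeled images) and the spec.
#' @export
gen_graded_dataset <- function(spec = fixture_spec(), n_per_grade = 100L,
                               labeled_fraction = 0.1,
                               n_heldout_per_grade = 25L, seed = 1L) {
  stopifnot(n_per_grade >= 1L, labeled_fraction > 0, labeled_fraction <= 1)
  set.seed(seed)
  lab_img <- list(); lab_y <- integer(); lab_nm <- character()
  lab_mask <- list()
  unl_img <- list(); unl_nm <- character(); unl_y <- integer()
  hld_img <- list(); hld_y <- integer(); hld_nm <- character()
  n_lab <- round(n_per_grade * labeled_fraction)
  for (g in 0:3) {
    for (i in seq_len(n_per_grade)) {
      fx <- gen_face_image(spec, g)
      nm <- sprintf("train_g%d_%04d.png", g, i)
      if (i <= n_lab) {
        lab_img[[length(lab_img) + 1L]] <- fx$image
        lab_mask[[length(lab_mask) + 1L]] <- fx$mask
        lab_y <- c(lab_y, g); lab_nm <- c(lab_nm, nm)
      } else {
        unl_img[[length(unl_img) + 1L]] <- fx$image
        unl_nm <- c(unl_nm, nm); unl_y <- c(unl_y, g)
      }
    }
    for (i in seq_len(n_heldout_per_grade)) {
      fx <- gen_face_image(spec, g)
      hld_img[[length(hld_img) + 1L]] <- fx$image
      hld_y <- c(hld_y, g)
      hld_nm <- c(hld_nm, sprintf("heldout_g%d_%04d.png", g, i))
    }
  }
  list(labeled = list(images = lab_img, labels = lab_y, names = lab_nm),
       masks = lab_mask,
       unlabeled = list(images = unl_img, names = unl_nm),
       unlabeled_truth = unl_y,
       heldout = list(images = hld_img, labels = hld_y, names = hld_nm),
       spec = spec, seed = seed)
}

#' Generate (image, mask) pairs for segmentation training
#'
#' Uniformly mixes grades so lesion pixels appear in the skin class.
#' @inheritParams gen_graded_dataset
#' @param n number of pairs.
#' @return list(images, masks, grades).
#' @export
gen_segmentation_pairs <- function(spec = fixture_spec(), n = 200L,
                                   seed = 1L) {
  set.seed(seed)
  grades <- rep(0:3, length.out = n)
  imgs <- vector("list", n); masks <- vector("list", n)
  for (i in seq_len(n)) {
    fx <- gen_face_image(spec, grades[i])
    imgs[[i]] <- fx$image; masks[[i]] <- fx$mask
  }
  list(images = imgs, masks = masks, grades = grades)
}

#' Write a fixture dataset to disk (PNG images, PNG masks, CSV manifests)
#'
#' @param ds a dataset from [gen_graded_dataset()].
#' @param dir output directory.
#' @return invisible `dir`.
#' @export
write_fixture_dir <- function(ds, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$labeled$images)) {
    write_image(ds$labeled$images[[i]],
                file.path(dir, "images", ds$labeled$names[i]))
    write_mask(ds$masks[[i]], file.path(dir, "masks", ds$labeled$names[i]))
  }
  for (i in seq_along(ds$unlabeled$images))
    write_image(ds$unlabeled$images[[i]],
                file.path(dir, "images", ds$unlabeled$names[i]))
  for (i in seq_along(ds$heldout$images))
    write_image(ds$heldout$images[[i]],
                file.path(dir, "images", ds$heldout$names[i]))
  utils::write.csv(data.frame(filename = ds$labeled$names,
                              grade = ds$labeled$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(data.frame(filename = ds$heldout$names,
                              grade = ds$heldout$labels),
                   file.path(dir, "heldout_labels.csv"), row.names = FALSE)
  writeLines(ds$unlabeled$names, file.path(dir, "unlabeled_manifest.txt"))
  invisible(dir)
}
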