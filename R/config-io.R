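# Dataset and configuration I/O plus the end-to-end pipeline: segment the
# facial-skin region of interest, train the feedback pseudo-label model,
# and evaluate on a held-out split.

#' Read a PNG image as an H x W x 3 array in \[0, 1\]
#'
#' Grayscale images are expanded to 3 channels; an alpha channel is
#' dropped. Only PNG is supported.
#' @param path file path.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("missing image file: ", path)
  if (!grepl("\\.png$", path, ignore.case = TRUE))
    stop("unsupported image format (only PNG is supported): ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an H x W x C array in \[0, 1\] as PNG
#' @param img image array.
#' @param path file path.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read / write a binary mask PNG ({0, 255} single channel)
#' @param path file path.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  (m >= 0.5) * 1
}

#' @rdname read_mask
#' @param mask binary matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask >= 0.5), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a labeled image dataset from a CSV manifest
#'
#' @param labels_csv CSV with columns `filename, grade` (grades 0-3).
#' @param image_dir directory holding the images.
#' @return list(images, labels, names, counts) where `counts` tabulates
#'   images per grade.
#' @export
read_graded_dataset <- function(labels_csv, image_dir) {
  df <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
  if (!all(c("filename", "grade") %in% names(df)))
    stop("labels CSV must have columns filename, grade")
  if (anyDuplicated(df$filename))
    stop("duplicate filename in labels CSV: ",
         df$filename[duplicated(df$filename)][1L])
  if (any(df$grade != as.integer(df$grade)) ||
      any(df$grade < 0L | df$grade > 3L))
    stop("grades must be integers in 0..3")
  images <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    p <- file.path(image_dir, df$filename[i])
    if (!file.exists(p))
      stop(sprintf("row %d: missing image file %s", i, df$filename[i]))
    images[[i]] <- read_image(p)
  }
  list(images = images, labels = as.integer(df$grade),
       names = df$filename,
       counts = table(factor(df$grade, levels = 0:3)))
}

#' Write / read a training configuration as YAML
#'
#' The YAML mirrors the config sections (`supervised`, `semi_supervised`,
#' `loss`, `augment`, `seed`) and round-trips exactly.
#' @param config an [aff_config()].
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(aff_config, raw)
}

#' Run the full grading pipeline on in-memory data
#'
#' Optionally crops every image to its predicted skin region, trains the
#' feedback pseudo-label model (or a supervised baseline), and evaluates
#' on the held-out split. Fully seeded through `config$seed`.
#'
#' @param labeled,unlabeled,heldout data splits as produced by
#'   [gen_graded_dataset()] (`unlabeled` may be a plain list of images).
#' @param config an [aff_config()].
#' @param segmenter optional trained [build_afss()] model; when given,
#'   all images are masked to their skin region first.
#' @param method `"aff"` or `"supervised"`.
#' @param augment apply the augmentation policy (supervised baseline) /
#'   the UDA branch policy (aff).
#' @param out_dir optional directory; writes `report.json` and
#'   `history.csv` when set.
#' @return list(fit, report) where `report` is the [evaluate_predictions()]
#'   output on the held-out split.
#' @export
run_pipeline <- function(labeled, unlabeled = NULL, heldout,
                         config = aff_config(), segmenter = NULL,
                         method = c("aff", "supervised"), augment = TRUE,
                         out_dir = NULL) {
  method <- match.arg(method)
  if (!is.null(unlabeled) && !is.null(unlabeled$images))
    unlabeled <- unlabeled$images
  crop <- function(imgs) lapply(imgs, function(im)
    segment_and_crop(segmenter, im)$image)
  if (!is.null(segmenter)) {
    labeled$images <- crop(labeled$images)
    heldout$images <- crop(heldout$images)
    if (!is.null(unlabeled)) unlabeled <- crop(unlabeled)
  }
  if (method == "aff") {
    if (is.null(unlabeled)) stop("aff method requires unlabeled images")
    if (!augment) config$augment$n_ops <- 0L
    fit <- aff_train(labeled, unlabeled, config)
  } else {
    fit <- supervised_train(labeled, config, augment = augment)
  }
  pred <- predict(fit, heldout$images)
  report <- evaluate_predictions(heldout$labels, pred,
                                 num_classes = max(heldout$labels) + 1L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(accuracy = report$macro$accuracy,
           precision = report$macro$precision,
           sensitivity = report$macro$sensitivity,
           specificity = report$macro$specificity,
           youden = report$macro$youden,
           per_class = report$per_class),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
  }
  list(fit = fit, report = report)
}

#' Module-ablation matrix on fixture data
#'
#' Reproduces the row structure of the module-comparison experiments:
#' a supervised baseline without any module, then the semi-supervised
#' framework with the segmentation (AFSS) and augmentation (AA) modules
#' toggled, reporting held-out accuracy and the delta to the baseline.
#'
#' @inheritParams run_pipeline
#' @param segmenter trained segmentation model used in the AFSS-on rows.
#' @return data frame with columns AFF, AFSS, AA, accuracy, delta.
#' @export
ablate <- function(labeled, unlabeled, heldout, config = aff_config(),
                   segmenter = NULL) {
  rows <- list(
    c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE),
    c(TRUE, FALSE, TRUE), c(TRUE, TRUE, TRUE)
  )
  acc <- numeric(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    res <- run_pipeline(labeled, unlabeled, heldout, config,
                        segmenter = if (r[2L]) segmenter else NULL,
                        method = if (r[1L]) "aff" else "supervised",
                        augment = r[3L])
    acc[i] <- res$report$macro$accuracy
  }
  out <- data.frame(AFF = vapply(rows, `[`, logical(1L), 1L),
                    AFSS = vapply(rows, `[`, logical(1L), 2L),
                    AA = vapply(rows, `[`, logical(1L), 3L),
                    accuracy = acc)
  out$delta <- out$accuracy - out$accuracy[1L]
  out
}
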