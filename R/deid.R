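# De-identification of clinical face images: identifiable features (eyes,
# eyebrows, mouth) are occluded with black rectangles, and filenames are
# replaced by the MD5 digest of their ASCII bytes. Occlusion boxes come
# from an external manifest (detector output or manual annotation) with
# 0-based, half-open pixel coordinates [x0, x1) x [y0, y1).

#' Zero out rectangular regions of an image
#'
#' Every pixel inside any box is set to 0 in all channels; all other
#' pixels are left bit-identical. Out-of-bounds boxes are clipped.
#'
#' @param image H x W x C array.
#' @param boxes data frame with columns `x0, y0, x1, y1` (0-based,
#'   half-open; x = column, y = row). A `region` label column is allowed
#'   and ignored here.
#' @return the masked image.
#' @export
mask_regions <- function(image, boxes) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  if (is.null(boxes) || nrow(boxes) == 0L) return(image)
  H <- dim(image)[1L]; W <- dim(image)[2L]
  for (i in seq_len(nrow(boxes))) {
    x0 <- max(0L, as.integer(boxes$x0[i])); y0 <- max(0L, as.integer(boxes$y0[i]))
    x1 <- min(W, as.integer(boxes$x1[i])); y1 <- min(H, as.integer(boxes$y1[i]))
    if (x1 <= x0 || y1 <= y0) next
    image[(y0 + 1L):y1, (x0 + 1L):x1, ] <- 0
  }
  image
}

#' MD5 digest of a filename's ASCII bytes
#'
#' @param name character scalar; must be encodable as ASCII unless
#'   `strict = FALSE`, in which case non-ASCII characters are transliterated
#'   by [iconv()].
#' @param strict error on non-ASCII input.
#' @return 32-character lowercase hex digest.
#' @export
hash_filename <- function(name, strict = TRUE) {
  stopifnot(is.character(name), length(name) == 1L)
  ascii <- iconv(name, to = "ASCII", sub = if (strict) NA else "?")
  if (is.na(ascii))
    stop("filename is not ASCII-encodable: ", name)
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(charToRaw(ascii), f)
  unname(tools::md5sum(f))
}

#' De-identify a directory of images
#'
#' Masks each image with its manifest boxes and writes it under the MD5
#' digest of its original name (without extension, by default). Output
#' PNGs are re-encoded from pixel data, so no source metadata survives.
#'
#' @param in_dir directory of PNG images.
#' @param boxes_manifest data frame with columns `filename, region, x0,
#'   y0, x1, y1` (multiple rows per file allowed), or a path to such a CSV.
#' @param out_dir output directory (created if missing).
#' @param hash_extension include the file extension in the hashed name.
#' @return invisible data frame mapping `original` to `hashed` filenames.
#' @export
deidentify_batch <- function(in_dir, boxes_manifest, out_dir,
                             hash_extension = FALSE) {
  if (is.character(boxes_manifest) && length(boxes_manifest) == 1L)
    boxes_manifest <- utils::read.csv(boxes_manifest, stringsAsFactors = FALSE)
  files <- list.files(in_dir, pattern = "\\.png$", ignore.case = TRUE)
  if (anyDuplicated(files)) stop("duplicate input filename")
  if (!is.null(boxes_manifest) && anyDuplicated(boxes_manifest) > 0)
    stop("duplicate manifest row")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    img <- read_image(file.path(in_dir, f))
    bx <- if (is.null(boxes_manifest)) NULL else
      boxes_manifest[boxes_manifest$filename == f, , drop = FALSE]
    img <- mask_regions(img, bx)
    stem <- if (hash_extension) f else sub("\\.[^.]+$", "", f)
    hashed <- paste0(hash_filename(stem), ".png")
    rows[[i]] <- data.frame(original = f, hashed = hashed)
    write_image(img, file.path(out_dir, hashed))
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(original = character(), hashed = character())
  if (anyDuplicated(manifest$hashed)) {
    dup <- manifest$hashed[duplicated(manifest$hashed)][1L]
    stop("digest collision between: ",
         paste(manifest$original[manifest$hashed == dup], collapse = ", "))
  }
  utils::write.csv(manifest, file.path(out_dir, "deid_manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
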