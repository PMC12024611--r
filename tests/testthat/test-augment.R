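# Augmentation policy: preset contents, the (N, M) grid, exclusion of
# color-disruptive transforms, determinism, and geometric/photometric
# safety properties.

test_that("the default policy has exactly the 8 lesion-safe transforms", {
  p <- aa_policy()
  expect_length(p$transforms, 8L)
  expect_setequal(names(p$transforms),
                  c("autocontrast", "brightness", "equalize", "rotate",
                    "shear_x", "shear_y", "translate_x", "translate_y"))
  expect_equal(unname(p$transforms[["rotate"]]), 1.3)
  expect_equal(unname(p$transforms[["equalize"]]), 0.3)
  # zeroing every scale gives the identity policy
  z <- aa_policy(overrides = stats::setNames(
    rep(0, 8), names(p$transforms)))
  expect_length(z$transforms, 0L)
  expect_error(aa_policy(overrides = c(warp = 1)), "unknown transform")
})

test_that("the comparison presets keep their own transform sets", {
  rc <- aa_policy("ra_cifar")
  expect_true(all(c("invert", "sample_pairing") %in% names(rc$transforms)))
  expect_equal(unname(rc$transforms[["posterize"]]), -0.3)
  rs <- aa_policy("ra_svhn")
  expect_false("rotate" %in% names(rs$transforms))
})

test_that("the policy grid is exactly the 10 x 10 search space", {
  g <- aa_policy_grid()
  expect_identical(nrow(g), 100L)
  expect_true(any(g$N == 1 & g$M == 1))
  expect_true(any(g$N == 10 & g$M == 10))
  expect_false(any(g$M == 0))
  expect_false(any(duplicated(g)))
})

test_that("applying zero ops or range-free ops leaves the image unchanged", {
  img <- rand_images(1, 12, 12, seed = 2)[[1L]]
  p0 <- aa_policy(n_ops = 0L)
  expect_identical(unclass(aa_apply(img, p0, seed = 1))[seq_along(img)],
                   img[seq_along(img)])
  # autocontrast on a constant image has no dynamic range to stretch
  const <- array(0.5, c(8, 8, 3))
  pc <- aa_policy(overrides = stats::setNames(
    c(1, rep(0, 7)), c("autocontrast", "brightness", "equalize", "rotate",
                       "shear_x", "shear_y", "translate_x", "translate_y")),
    n_ops = 1L, magnitude = 10L)
  out <- aa_apply(const, pc, seed = 3)
  expect_equal(array(out, dim(const)), const, tolerance = 1e-12)
})

test_that("augmentation is a pure function of (image, policy, seed)", {
  img <- rand_images(1, 16, 16, seed = 4)[[1L]]
  p <- aa_policy(n_ops = 2L, magnitude = 9L)
  a <- aa_apply(img, p, seed = 7)
  b <- aa_apply(img, p, seed = 7)
  expect_identical(a, b)
  d <- aa_apply(img, p, seed = 8)
  expect_false(identical(array(a, dim(img)), array(d, dim(img))))
})

test_that("excluded transforms are never sampled over 10,000 seeded draws", {
  img <- rand_images(1, 8, 8, seed = 5)[[1L]]
  p <- aa_policy(n_ops = 2L, magnitude = 9L)
  excluded <- c("color", "contrast", "invert", "posterize", "solarize",
                "sharpness", "sample_pairing")
  seen <- character(0)
  set.seed(1234)
  for (i in seq_len(10000L)) {
    out <- aa_apply(img, p)
    seen <- union(seen, attr(out, "ops"))
  }
  expect_length(intersect(seen, excluded), 0L)
  # every active transform does eventually appear
  expect_setequal(seen, names(p$transforms))
})

test_that("every active transform preserves image dimensions", {
  img <- rand_images(1, 20, 14, seed = 6)[[1L]]
  p <- aa_policy(magnitude = 10L)
  ns <- asNamespace("acnegrader")
  set.seed(2)
  for (nm in names(p$transforms)) {
    out <- ns$apply_one_transform(img, nm, p$transforms[[nm]], 10L)
    expect_identical(dim(out), dim(img))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("non-geometric retained transforms are channel-monotone", {
  # autocontrast and equalize must preserve the within-channel ordering of
  # pixel values (monotone intensity maps), so chromatic evidence ordering
  # survives augmentation
  ns <- asNamespace("acnegrader")
  set.seed(8)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  for (fn in list(function(x) ns$tf_autocontrast(x, 1),
                  function(x) ns$tf_equalize(x, 1))) {
    out <- fn(img)
    for (ch in 1:3) {
      o <- order(img[, , ch])
      expect_true(all(diff(out[, , ch][o]) >= -1e-12))
    }
  }
})
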