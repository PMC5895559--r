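# Automatic MTV delineation methods

exact_methods <- c("AT", "KM2", "FCM2", "RG", "GCM3")

test_that("separable two-level lesions are delineated exactly", {
  ph <- two_level_phantom()
  box <- truth_bounding_box(ph$truth$mask, 8)
  for (m in exact_methods) {
    r <- segment_mtv(ph$volume, box, m)
    expect_false(r$failed, info = m)
    expect_equal(dice(r$mask, ph$truth$mask), 1.0, info = m)
  }
  wt <- segment_mtv(ph$volume, box, "WT")
  expect_gte(dice(wt$mask, ph$truth$mask), 0.90)
})

test_that("adaptive threshold converges to the two-level fixed point", {
  ph <- two_level_phantom()
  box <- truth_bounding_box(ph$truth$mask, 8)
  r <- segment_at(ph$volume, box, w = 0.5)
  expect_equal(r$diagnostics$threshold, 6.0)
  # the converged fixed point does not depend on the tolerance
  r2 <- segment_at(ph$volume, box, tol = 5e-4)
  expect_identical(r2$mask, r$mask)
})

test_that("uniform volumes fail cleanly for every method", {
  vol <- tiny_volume(array(3, c(12, 12, 12)))
  box <- bounding_box(c(1, 1, 1), c(11, 11, 11), c(12, 12, 12))
  for (m in c("AT", "KM2", "FCM2", "GCM3", "WT")) {
    r <- segment_mtv(vol, box, m)
    expect_true(r$failed, info = m)
  }
})

test_that("k-means is deterministic and matches Lloyd's algorithm", {
  ph <- moderate_phantom(21)
  box <- truth_bounding_box(ph$truth$mask, 8)
  a <- segment_km(ph$volume, box, k = 2, seed = 1L)
  b <- segment_km(ph$volume, box, k = 2, seed = 999L)
  expect_identical(a$mask, b$mask)
  # cross-check the converged centres against stats::kmeans started from
  # the same initial centres
  x <- as.vector(petrad:::crop_box(ph$volume$values, box))
  init <- petrad:::range_centres(x, 2)
  km <- stats::kmeans(x, matrix(init), algorithm = "Lloyd",
                      iter.max = 100)
  expect_equal(sort(as.vector(km$centers)),
               sort(a$diagnostics$centres), tolerance = 1e-6)
})

test_that("fuzzy memberships are a partition of unity and match cmeans", {
  skip_if_not_installed("e1071")
  ph <- moderate_phantom(22)
  box <- truth_bounding_box(ph$truth$mask, 8)
  x <- as.vector(petrad:::crop_box(ph$volume$values, box))
  fit <- petrad:::fcm_cluster(x, 2, m = 2, tol = 1e-6, max_iter = 200)
  expect_equal(rowSums(fit$memberships), rep(1, length(x)),
               tolerance = 1e-12)
  ref <- e1071::cmeans(matrix(x), centers = matrix(petrad:::range_centres(x, 2)),
                       m = 2, iter.max = 200, method = "cmeans")
  expect_equal(sort(fit$centres), sort(as.vector(ref$centers)),
               tolerance = 1e-2)
})

test_that("fuzzy c-means overestimates homogeneous low-contrast lesions", {
  # low TBR with heavy blur: the membership boundary lands outside the
  # true edge, inflating the volume
  ratio <- sapply(1:20, function(s) {
    ph <- generate_phantom(phantom_spec(
      lesion_mean_suv = 3, background_mean_suv = 2, heterogeneity_sd = 0,
      psf_fwhm_mm = 10, noise_sd = 0.1, seed = 3000L + s))
    box <- truth_bounding_box(ph$truth$mask, 8)
    r <- segment_fcm(ph$volume, box)
    if (r$failed) return(NA_real_)
    sum(r$mask) / sum(ph$truth$mask)
  })
  expect_gt(median(ratio, na.rm = TRUE), 1)
})

test_that("EM log-likelihood is non-decreasing and recovers separated mixtures", {
  # three spatially arranged, well-separated intensity classes
  dm <- c(12, 12, 12)
  set.seed(4)
  vals <- array(rnorm(prod(dm), 2, 0.1), dm)
  vals[5:12, , ] <- rnorm(8 * 12 * 12, 5, 0.1)
  vals[9:12, , ] <- rnorm(4 * 12 * 12, 9, 0.1)
  vol <- tiny_volume(pmax(vals, 0))
  box <- bounding_box(c(0, 0, 0), dm, dm)
  r <- segment_gcm(vol, box, k = 3, tol = 1e-8)
  expect_false(r$failed)
  ll <- r$diagnostics$loglik_trace
  expect_true(all(diff(ll) > -1e-6))
  expect_equal(sort(r$diagnostics$means), c(2, 5, 9), tolerance = 0.1)
  truth <- array(FALSE, dm); truth[9:12, , ] <- TRUE
  expect_gte(dice(r$mask, truth), 0.95)
})

test_that("gaussian mixture means agree with mclust on the same data", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))    # Mclust needs its namespace attached
  # well-separated mixture: the global optimum is unambiguous, so two
  # independent EM implementations must agree
  set.seed(23)
  x <- c(rnorm(500, 2, 0.2), rnorm(300, 5, 0.3), rnorm(200, 9, 0.3))
  fit <- petrad:::gmm_em(x, 3, tol = 1e-8, max_iter = 500)
  ref <- Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.vector(ref$parameters$mean)),
               tolerance = 0.05)
})

test_that("over-clustering fails at least as often as the retained variant", {
  n_fail <- c(GCM3 = 0L, GCM4 = 0L, KM2 = 0L, KM4 = 0L)
  for (s in 1:50) {
    ph <- moderate_phantom(5000L + s)
    box <- truth_bounding_box(ph$truth$mask, 8)
    for (m in names(n_fail)) {
      r <- segment_mtv(ph$volume, box, m)
      if (flag_failed_contour(r, box, ph$truth))
        n_fail[m] <- n_fail[m] + 1L
    }
  }
  expect_gte(n_fail[["GCM4"]], n_fail[["GCM3"]])
  expect_gte(n_fail[["KM4"]], n_fail[["KM2"]])
})

test_that("unconstrained region growing floods to the box boundary", {
  ph <- two_level_phantom()
  box <- truth_bounding_box(ph$truth$mask, 8)
  r <- segment_rg(ph$volume, box, f = 0)
  expect_true(r$failed)
})

test_that("region growing degrades on highly heterogeneous lesions", {
  dice_for <- function(het, s) {
    ph <- generate_phantom(phantom_spec(
      lesion_mean_suv = 8, background_mean_suv = 2,
      heterogeneity_sd = het, psf_fwhm_mm = 4, noise_sd = 0.2,
      seed = 6000L + s))
    box <- truth_bounding_box(ph$truth$mask, 8)
    r <- segment_rg(ph$volume, box)
    if (r$failed) 0 else dice(r$mask, ph$truth$mask)
  }
  d_hom <- sapply(1:20, dice_for, het = 0.2)
  d_het <- sapply(1:20, dice_for, het = 4.0)
  expect_lt(median(d_het), median(d_hom))
})

test_that("watershed accuracy does not improve when blur doubles", {
  dice_for <- function(fwhm, s) {
    ph <- generate_phantom(phantom_spec(
      lesion_mean_suv = 8, background_mean_suv = 2, heterogeneity_sd = 0.5,
      psf_fwhm_mm = fwhm, noise_sd = 0.2, seed = 7000L + s))
    box <- truth_bounding_box(ph$truth$mask, 8)
    r <- segment_wt(ph$volume, box)
    if (r$failed) 0 else dice(r$mask, ph$truth$mask)
  }
  d1 <- sapply(1:20, dice_for, fwhm = 5)
  d2 <- sapply(1:20, dice_for, fwhm = 10)
  expect_lte(median(d2), median(d1))
})

test_that("returned masks are single 26-connected components inside the box", {
  ph <- moderate_phantom(31)
  box <- truth_bounding_box(ph$truth$mask, 8)
  outside <- !petrad:::embed_box(array(TRUE, petrad:::box_dims(box)), box,
                                 dim(ph$volume$values))
  for (m in PETAS_METHODS) {
    r <- segment_mtv(ph$volume, box, m)
    if (r$failed) next
    expect_equal(sum(r$mask & outside), 0, info = m)
    lab <- petrad:::label_components(r$mask)
    expect_equal(max(lab), 1L, info = m)
  }
})

test_that("the contour screen flags box conformance, emptiness and mismatch", {
  ph <- two_level_phantom()
  box <- truth_bounding_box(ph$truth$mask, 8)
  grid <- dim(ph$volume$values)
  full_box <- petrad:::embed_box(array(TRUE, petrad:::box_dims(box)), box,
                                 grid)
  mk <- function(mask, failed = FALSE)
    structure(list(method_name = "AT", mask = mask, failed = failed),
              class = "segmentation_result")
  expect_true(flag_failed_contour(mk(full_box), box))
  expect_true(flag_failed_contour(mk(array(FALSE, grid)), box))
  expect_false(flag_failed_contour(mk(ph$truth$mask), box, ph$truth))
  # Dice just under the threshold fails: a small blob inside the lesion
  co <- which(ph$truth$mask, arr.ind = TRUE)
  blob <- array(FALSE, grid)
  blob[co[1:22, , drop = FALSE]] <- TRUE
  stopifnot(dice(blob, ph$truth$mask) < 0.30)
  expect_true(flag_failed_contour(mk(blob), box, ph$truth))
})

test_that("standard methods pass the screen on most moderate phantoms", {
  methods <- c("AT", "KM2", "GCM3", "WT")
  ok <- setNames(numeric(length(methods)), methods)
  n_batch <- 100
  for (s in seq_len(n_batch)) {
    ph <- moderate_phantom(8000L + s)
    box <- truth_bounding_box(ph$truth$mask, 8)
    for (m in methods) {
      r <- segment_mtv(ph$volume, box, m)
      if (!flag_failed_contour(r, box, ph$truth)) ok[m] <- ok[m] + 1
    }
  }
  for (m in methods) expect_gte(ok[[m]] / n_batch, 0.90)
})
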