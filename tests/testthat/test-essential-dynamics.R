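test_that("static ensembles have an all-zero eigenspectrum", {
  ens <- generate_ensemble(ensemble_spec(5, 5, fluctuation = 0, seed = 1))
  ed <- fit_essential_dynamics(ens, "calpha")
  expect_equal(max(abs(ed$eigenvalues)), 0, tolerance = 1e-12)
})

test_that("a single moving atom gives one eigenvalue equal to its variance", {
  m <- gly_tripeptide()
  base <- as.matrix(m[, c("x", "y", "z")])
  up <- base
  down <- base
  up[2, 1] <- up[2, 1] + 1 # +-1 A = +-0.1 nm along x
  down[2, 1] <- down[2, 1] - 1
  ens <- ens_from_frames(m, list(up, down, up, down))
  ed <- fit_essential_dynamics(ens, "all", fit = FALSE)
  expect_equal(ed$eigenvalues[1], 0.01, tolerance = 1e-10)
  expect_equal(max(abs(ed$eigenvalues[-1])), 0, tolerance = 1e-12)
  v <- ed$eigenvectors[, 1]
  expect_equal(abs(v[4]), 1, tolerance = 1e-9) # atom 2, x component
})

test_that("covariance trace equals the eigenvalue sum", {
  ens <- generate_ensemble(ensemble_spec(8, 25, fluctuation = 0.4, seed = 19))
  ed <- fit_essential_dynamics(ens, "backbone")
  expect_equal(sum(ed$eigenvalues), ed$trace, tolerance = 1e-8 * ed$trace)
})

test_that("projection variance reproduces the eigenvalues exactly", {
  ens <- generate_ensemble(ensemble_spec(8, 30, fluctuation = 0.3, seed = 2))
  ed <- fit_essential_dynamics(ens, "calpha")
  pr <- project_ensemble(ens, ed, k = 3)
  for (i in 1:3) {
    p <- pr[[paste0("pc", i)]]
    expect_equal(mean((p - mean(p))^2), ed$eigenvalues[i],
      tolerance = 1e-8 * max(ed$eigenvalues[1], 1e-12)
    )
    expect_equal(mean(p), 0, tolerance = 1e-8)
  }
})

test_that("full-rank back-projection reconstructs the fitted coordinates", {
  ens <- generate_ensemble(ensemble_spec(5, 12, fluctuation = 0.3, seed = 3))
  ed <- fit_essential_dynamics(ens, "calpha")
  k <- length(ed$eigenvalues)
  pr <- project_ensemble(ens, ed, k = k)
  P <- as.matrix(pr[, paste0("pc", seq_len(k))])
  X <- P %*% t(ed$eigenvectors) + matrix(ed$center, nrow(P), 3 * 5, byrow = TRUE)
  X_direct <- rinflow:::.project_frames_nm(ens, ed$selection, ed$fit_target)
  expect_equal(X, X_direct, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("projecting the mean structure gives the zero vector", {
  ens <- generate_ensemble(ensemble_spec(5, 20, fluctuation = 0.2, seed = 5))
  ed <- fit_essential_dynamics(ens, "calpha")
  mean_model <- ens$topology[ed$selection, ]
  mean_model$x <- ed$mean_coordinates[, 1]
  mean_model$y <- ed$mean_coordinates[, 2]
  mean_model$z <- ed$mean_coordinates[, 3]
  ens_mean <- trajectory_ensemble(
    mean_model,
    array(as.matrix(mean_model[, c("x", "y", "z")]), c(1, nrow(mean_model), 3))
  )
  ed_local <- ed
  ed_local$selection <- seq_len(nrow(mean_model))
  pr <- project_ensemble(ens_mean, ed_local, k = 2)
  expect_equal(as.numeric(pr[1, c("pc1", "pc2")]), c(0, 0), tolerance = 1e-6)
})

test_that("the eigenspectrum ignores a common rigid translation", {
  ens <- generate_ensemble(ensemble_spec(6, 15, fluctuation = 0.3, seed = 7))
  ed <- fit_essential_dynamics(ens, "calpha")
  shifted <- ens$coords
  for (i in seq_len(n_frames(ens))) shifted[i, , ] <- shifted[i, , ] + 25
  ens2 <- trajectory_ensemble(ens$topology, shifted, times = ens$times)
  ed2 <- fit_essential_dynamics(ens2, "calpha")
  expect_equal(ed2$eigenvalues, ed$eigenvalues, tolerance = 1e-8)
})

test_that("cumulative variance is non-decreasing and reaches one", {
  ens <- generate_ensemble(ensemble_spec(6, 40, fluctuation = 0.5, seed = 11))
  td <- tidy(fit_essential_dynamics(ens, "calpha"))
  expect_true(all(diff(td$cumulative_fraction) >= -1e-12))
  expect_equal(td$cumulative_fraction[nrow(td)], 1, tolerance = 1e-8)
})

test_that("the designed collective mode is recovered as PC1", {
  spec <- ensemble_spec(10, 50,
    fluctuation = 0.05,
    collective_mode = list(amplitude = 2.5), seed = 13
  )
  ens <- generate_ensemble(spec)
  ed <- fit_essential_dynamics(ens, "all")
  D <- attr(ens, "design")$mode_direction
  cosim <- abs(sum(ed$eigenvectors[, 1] * as.numeric(t(D))))
  expect_gt(cosim, 0.99)
})

test_that("cosine content matches its definitional limits", {
  t <- seq(0, 100, length.out = 1000)
  make_series <- function(p) {
    out <- tibble::tibble(time = t, pc1 = p)
    class(out) <- c("projection_series", class(out))
    out
  }
  expect_equal(cosine_content(make_series(cos(pi * t / 100)), 1), 1, tolerance = 0.01)
  expect_equal(cosine_content(make_series(cos(2 * pi * t / 100)), 1), 0, tolerance = 0.01)
  for (s in 1:5) {
    set.seed(s)
    expect_lt(cosine_content(make_series(rnorm(1000)), 1), 0.2)
  }
  expect_warning(cc0 <- cosine_content(make_series(rep(0, 1000)), 1), "All-zero")
  expect_equal(cc0, 0)
})

test_that("Boltzmann inversion matches the two-bin closed form", {
  series <- tibble::tibble(
    time = seq_len(100) - 1,
    pc1 = c(rep(-1, 80), rep(1, 20)),
    pc2 = rep(0, 100)
  )
  class(series) <- c("projection_series", class(series))
  fel <- free_energy_surface(series, n_bins = 4, temperature = 300, force = TRUE)
  expect_equal(sum(fel$counts), 100)
  dg <- sort(unique(fel$delta_g[is.finite(fel$delta_g)]))
  expect_equal(dg[1], 0)
  expect_equal(dg[2], 0.0083145 * 300 * log(4), tolerance = 1e-6)
})

test_that("single-occupied-bin surfaces put all frames at the minimum", {
  series <- tibble::tibble(time = 0:9, pc1 = rep(0.5, 10), pc2 = rep(-0.5, 10))
  class(series) <- c("projection_series", class(series))
  fel <- free_energy_surface(series, n_bins = 5, force = TRUE)
  expect_equal(sum(fel$counts > 0), 1)
  expect_equal(fel$delta_g[which(fel$counts > 0)], 0)
  expect_equal(locate_minimum_frames(fel, series), 1:10)
})

test_that("minimum-basin frames come from the larger cluster, in bin", {
  series <- tibble::tibble(
    time = 0:9,
    pc1 = c(rep(-2, 6), rep(2, 4)), pc2 = rep(0, 10)
  )
  class(series) <- c("projection_series", class(series))
  fel <- free_energy_surface(series, n_bins = 4, force = TRUE)
  frames <- locate_minimum_frames(fel, series)
  expect_equal(frames, 1:6)
  expect_true(all(series$pc1[frames] >= fel$edges_x[1] &
    series$pc1[frames] <= fel$edges_x[length(fel$edges_x)]))
})

test_that("landscapes refuse unconverged projections unless forced", {
  set.seed(99)
  t <- 0:199
  series <- tibble::tibble(
    time = t, pc1 = cos(pi * t / 199) + rnorm(200, sd = 1e-3),
    pc2 = rnorm(200)
  )
  class(series) <- c("projection_series", class(series))
  expect_gt(cosine_content(series, 1), 0.2)
  expect_error(free_energy_surface(series), "Cosine content")
  expect_s3_class(free_energy_surface(series, force = TRUE), "free_energy_surface")
  expect_error(free_energy_surface(series, n_bins = 3, force = TRUE), "at least 4")
})
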