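test_that("superposition recovers identity, translation and rotation exactly", {
  m <- gly_tripeptide()
  X <- as.matrix(m[, c("x", "y", "z")])
  expect_equal(superpose(X, X)$rmsd, 0, tolerance = 1e-10)
  expect_equal(superpose(sweep(X, 2, c(5, 0, 0), `+`), X)$rmsd, 0, tolerance = 1e-10)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3) # 90 degrees about z
  fit <- superpose(X %*% t(Rz), X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(t(fit$rotation) %*% fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("degenerate fits are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(line[1:2, ], line[1:2, ]), "at least 3")
})

test_that("fit RMSD matches a direct numerical minimisation oracle", {
  set.seed(31)
  for (rep in 1:3) {
    ref <- matrix(rnorm(15, sd = 3), 5, 3)
    mob <- ref + matrix(rnorm(15, sd = 0.4), 5, 3)
    got <- superpose(mob, ref)$rmsd
    expect_equal(got, oracle_fit_rmsd(mob, ref), tolerance = 1e-5)
  }
})

test_that("single-atom displacement gives post-fit RMSD below the raw shift", {
  m <- gly_tripeptide()
  base <- as.matrix(m[, c("x", "y", "z")])
  moved <- base
  moved[5, 3] <- moved[5, 3] + 1 # 1 A on one of 12 atoms
  ens <- ens_from_frames(m, list(base, base, moved))
  rs <- rmsd_series(ens, "all")
  expect_equal(rs$rmsd[1:2], c(0, 0), tolerance = 1e-10)
  expect_gt(rs$rmsd[3], 0)
  expect_lt(rs$rmsd[3], 1)
  expect_equal(rs$rmsd[3], oracle_fit_rmsd(moved, base), tolerance = 1e-5)
})

test_that("RMSD is symmetric and invariant to atom order in the selection", {
  m <- gly_tripeptide()
  base <- as.matrix(m[, c("x", "y", "z")])
  set.seed(8)
  other <- base + matrix(rnorm(length(base), sd = 0.5), nrow(base))
  expect_equal(
    superpose(other, base)$rmsd, superpose(base, other)$rmsd,
    tolerance = 1e-9
  )
  sel <- 1:8
  perm <- sample(sel)
  expect_equal(
    superpose(other, base, selection = sel)$rmsd,
    superpose(other, base, selection = perm)$rmsd,
    tolerance = 1e-9
  )
})

test_that("two-point alternation gives RMSF equal to the amplitude", {
  m <- gly_tripeptide()
  base <- as.matrix(m[, c("x", "y", "z")])
  up <- base
  down <- base
  ca2 <- which(m$name == "CA")[2]
  a <- 0.7
  up[ca2, 1] <- up[ca2, 1] + a
  down[ca2, 1] <- down[ca2, 1] - a
  ens <- ens_from_frames(m, list(up, down, up, down))
  fixed <- setdiff(seq_len(nrow(m)), ca2)
  out <- rmsf_table(ens, selection = "calpha", fit_selection = fixed)
  expect_equal(out$rmsf[2], a, tolerance = 1e-9)
  expect_equal(out$rmsf[c(1, 3)], c(0, 0), tolerance = 1e-9)
})

test_that("isotropic Gaussian noise yields RMSF near sigma * sqrt(3)", {
  sigma <- 0.3
  ens <- generate_ensemble(ensemble_spec(20, 300, fluctuation = sigma, seed = 13))
  out <- rmsf_table(ens, selection = "calpha", fit_selection = "protein")
  expect_equal(mean(out$rmsf), sigma * sqrt(3), tolerance = 0.05)
})

test_that("RMSF is invariant to a rigid motion applied to every frame", {
  ens <- generate_ensemble(ensemble_spec(6, 20, fluctuation = 0.3, seed = 17))
  ref <- rmsf_table(ens, "calpha")
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  moved <- ens$coords
  for (i in seq_len(n_frames(ens))) {
    moved[i, , ] <- sweep(moved[i, , ] %*% t(Rz), 2, c(10, -4, 2), `+`)
  }
  ens2 <- trajectory_ensemble(ens$topology, moved, times = ens$times)
  expect_equal(rmsf_table(ens2, "calpha")$rmsf, ref$rmsf, tolerance = 1e-8)
})

test_that("SASA matches closed forms for isolated and overlapping spheres", {
  one <- make_atoms("O", "O", 1, 0, 0, 0)
  one$element <- "O"
  ens1 <- ens_from_frames(one, list(cbind(0, 0, 0)))
  radii <- c(O = 0.14)
  s1 <- sasa_series(ens1, "all", probe_radius = 0.14, n_points = 960, radii = radii)
  expect_equal(s1$sasa, 4 * pi * 0.28^2, tolerance = 0.01)
  two <- make_atoms(c("O", "O"), c("O", "O"), c(1, 2), c(0, 0), c(0, 0), c(0, 0))
  ens2 <- ens_from_frames(two, list(matrix(0, 2, 3)))
  s2 <- sasa_series(ens2, "all", probe_radius = 0.14, n_points = 960, radii = radii)
  expect_equal(s2$sasa, s1$sasa, tolerance = 1e-9) # coincident spheres
  far <- make_atoms(c("O", "O"), c("O", "O"), c(1, 2), c(0, 20), c(0, 0), c(0, 0))
  ens3 <- ens_from_frames(far, list(as.matrix(far[, c("x", "y", "z")])))
  s3 <- sasa_series(ens3, "all", probe_radius = 0.14, n_points = 960, radii = radii)
  expect_equal(s3$sasa, 2 * s1$sasa, tolerance = 1e-9)
})

test_that("pair SASA is non-increasing as a second atom approaches", {
  radii <- c(O = 0.14)
  vals <- vapply(seq(8, 0.5, by = -0.5), function(d) {
    two <- make_atoms(c("O", "O"), c("O", "O"), c(1, 2), c(0, d), c(0, 0), c(0, 0))
    ens <- ens_from_frames(two, list(as.matrix(two[, c("x", "y", "z")])))
    sasa_series(ens, "all", probe_radius = 0.14, n_points = 480, radii = radii)$sasa
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("unknown element radii are reported by name", {
  odd <- make_atoms("FE", "FE", 1, 0, 0, 0)
  ens <- ens_from_frames(odd, list(cbind(0, 0, 0)))
  expect_error(sasa_series(ens, "all"), "FE")
})
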