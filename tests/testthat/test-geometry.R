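as_xyz_df <- function(d) as.matrix(d[c("x", "y", "z")])

test_that("superposition recovers identity and pure translations exactly", {
  set.seed(1)
  X <- matrix(stats::rnorm(30, sd = 5), ncol = 3)
  same <- superpose(X, X)
  expect_equal(same$rmsd, 0, tolerance = 1e-9)
  expect_equal(same$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(same$transform$translation, c(0, 0, 0), tolerance = 1e-9)

  shifted <- superpose(X, X + rep(c(1, 2, 3), each = nrow(X)))
  expect_equal(shifted$transform$translation, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(shifted$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(shifted$rmsd, 0, tolerance = 1e-9)
})

test_that("superposition recovers a known rigid transform on clean points", {
  set.seed(2)
  for (i in 1:5) {
    X <- matrix(stats::rnorm(60, sd = 8), ncol = 3)
    op <- random_transform()
    fit <- superpose(X, apply_transform(op, X))
    expect_equal(fit$rmsd, 0, tolerance = 1e-8)
    expect_equal(fit$transform$rotation, op$rotation, tolerance = 1e-8)
    expect_equal(fit$transform$translation, op$translation, tolerance = 1e-7)
  }
})

test_that("superposition never returns a reflection, even for mirrored inputs", {
  set.seed(3)
  X <- matrix(stats::rnorm(45, sd = 5), ncol = 3)
  mirrored <- X %*% diag(c(-1, 1, 1))
  fit <- superpose(X, mirrored)
  expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.1)  # a mirror image cannot be fit rigidly
})

test_that("degenerate configurations are refused", {
  expect_error(superpose(matrix(stats::rnorm(6), ncol = 3),
                         matrix(stats::rnorm(6), ncol = 3)),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(matrix(stats::rnorm(30), ncol = 3),
                         matrix(stats::rnorm(15), ncol = 3)),
               "differ")
})

test_that("no small rotation perturbation improves the returned superposition", {
  set.seed(4)
  X <- matrix(stats::rnorm(60, sd = 6), ncol = 3)
  Y <- apply_transform(random_transform(), X) +
    matrix(stats::rnorm(60, sd = 0.5), ncol = 3)
  fit <- superpose(X, Y)
  rmsd_for <- function(R) {
    t_vec <- colMeans(Y) - as.numeric(R %*% colMeans(X))
    sqrt(mean(rowSums((X %*% t(R) + rep(t_vec, each = nrow(X)) - Y)^2)))
  }
  for (i in 1:50) {
    wiggle <- screw_to_transform(list(axis = stats::rnorm(3), point = c(0, 0, 0),
                                      twist = stats::runif(1, -2, 2), rise = 0))
    expect_gte(rmsd_for(wiggle$rotation %*% fit$transform$rotation) + 1e-12,
               fit$rmsd)
  }
})

test_that("superposition agrees with an independent least-squares routine", {
  set.seed(5)
  X <- matrix(stats::rnorm(60, sd = 6), ncol = 3)
  Y <- apply_transform(random_transform(), X) +
    matrix(stats::rnorm(60, sd = 0.8), ncol = 3)
  fit <- superpose(X, Y)
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(Y)), mobile = as.numeric(t(X))))
  ref_rmsd <- sqrt(mean(colSums(matrix(ref - as.numeric(t(Y)), nrow = 3)^2)))
  expect_equal(fit$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("screw decomposition matches closed-form constructions", {
  id <- screw_decompose(rigid_transform())
  expect_equal(id$twist, 0)
  expect_equal(id$rise, 0)

  helix <- rotation_about_axis(c(0, 0, 1), 60, c(0, 0, 5))
  s <- screw_decompose(helix)
  expect_equal(s$twist, 60, tolerance = 1e-9)
  expect_equal(s$rise, 5, tolerance = 1e-9)
  expect_equal(abs(s$axis[3]), 1, tolerance = 1e-9)

  slide <- rigid_transform(diag(3), c(3, 4, 0))
  s2 <- screw_decompose(slide)
  expect_equal(s2$twist, 0)
  expect_equal(s2$rise, 5)  # |t|
  expect_equal(s2$axis, c(0.6, 0.8, 0))
})

test_that("screw parameters reconstruct their transform for random operators", {
  set.seed(6)
  pts <- matrix(stats::rnorm(30, sd = 10), ncol = 3)
  for (i in 1:20) {
    op <- random_transform()
    back <- screw_to_transform(screw_decompose(op))
    expect_equal(apply_transform(back, pts), apply_transform(op, pts),
                 tolerance = 1e-6)
  }
  # half-turn edge case
  half <- rotation_about_axis(c(0, 1, 0), 180, c(0, 2, 0))
  back <- screw_to_transform(screw_decompose(half))
  expect_equal(apply_transform(back, pts), apply_transform(half, pts),
               tolerance = 1e-6)
})

test_that("repeats advance n x rise along the screw axis", {
  set.seed(7)
  op <- random_transform()
  s <- screw_decompose(op)
  dom <- make_toy_domain(10)
  chain <- propagate_chain(dom, op, 10)
  centroids <- t(vapply(chain$copies,
                        function(d) colMeans(as.matrix(d[c("x", "y", "z")])),
                        numeric(3)))
  axial <- as.numeric(centroids %*% s$axis)
  expect_equal(diff(axial), rep(s$rise, 9), tolerance = 1e-6)
})

test_that("transform composition and inversion behave as a group", {
  set.seed(8)
  pts <- matrix(stats::rnorm(30, sd = 5), ncol = 3)
  op <- random_transform()
  # op^m o op^k = op^(m+k)
  lhs <- apply_transform(compose_transform(transform_power(op, 3),
                                           transform_power(op, 2)), pts)
  rhs <- apply_transform(transform_power(op, 5), pts)
  expect_equal(lhs, rhs, tolerance = 1e-6)
  # n forward then n backward restores coordinates
  there <- apply_transform(transform_power(op, 4), pts)
  back <- apply_transform(transform_power(invert_transform(op), 4), there)
  expect_equal(back, pts, tolerance = 1e-6)
})

test_that("chain propagation equals matrix-power composition", {
  dom <- make_toy_domain(12)
  expect_equal(propagate_chain(dom, random_transform(), 1)$copies[[1]], dom)

  slide <- rigid_transform(diag(3), c(2, 0, 0))
  chain <- propagate_chain(dom, slide, 4)
  for (k in 0:3) {
    expect_equal(chain$copies[[k + 1]]$x, dom$x + 2 * k, tolerance = 1e-9)
  }

  set.seed(9)
  op <- random_transform()
  chain6 <- propagate_chain(dom, op, 6)
  for (k in 0:5) {
    expect_equal(as_xyz_df(chain6$copies[[k + 1]]),
                 as_xyz_df(apply_transform(transform_power(op, k), dom)),
                 tolerance = 1e-6)
  }
  expect_error(propagate_chain(dom, op, 0), ">= 1")
})

test_that("rigid transforms reject reflections at construction", {
  expect_error(rigid_transform(diag(c(-1, 1, 1))), "det")
  expect_error(rigid_transform(matrix(stats::rnorm(9), 3)), "orthonormal|det")
})

test_that("clash counts equal an all-pairs brute-force oracle", {
  dom <- make_toy_domain(10)
  # two copies superposed: every cross pair within cutoff
  worst <- propagate_chain(dom, rigid_transform(), 3)
  cc <- clash_check(worst, cutoff = 1e6)
  expect_equal(cc$n_clashes, nrow(dom)^2)           # copies 1-3
  expect_equal(cc$n_interface_contacts, 2 * nrow(dom)^2)
  # rise far larger than the domain: no contacts at all
  far <- propagate_chain(dom, rigid_transform(diag(3), c(0, 0, 500)), 4)
  expect_equal(clash_check(far, 4)$n_clashes, 0)
  expect_equal(clash_check(far, 4)$n_interface_contacts, 0)
  # random chain vs double-loop oracle
  set.seed(10)
  chain <- propagate_chain(dom, rigid_transform(random_rotation(), c(3, 1, 2)), 5)
  cutoff <- 6
  oracle <- 0L
  for (i in 1:5) for (j in 1:5) {
    if (j - i >= 2) {
      A <- as.matrix(chain$copies[[i]][c("x", "y", "z")])
      B <- as.matrix(chain$copies[[j]][c("x", "y", "z")])
      for (a in seq_len(nrow(A))) for (b in seq_len(nrow(B))) {
        if (sum((A[a, ] - B[b, ])^2) < cutoff^2) oracle <- oracle + 1L
      }
    }
  }
  expect_equal(clash_check(chain, cutoff)$n_clashes, oracle)
  expect_error(clash_check(propagate_chain(dom, rigid_transform(), 1)),
               "at least 2")
})
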