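test_that("landmark similarity recovers identity, pure scaling, and planted transforms", {
  set.seed(3)
  X <- matrix(rnorm(15), ncol = 3)
  idn <- landmark_similarity(X, X)
  expect_equal(idn$scale, 1, tolerance = 1e-12)
  expect_equal(idn$rotation, diag(3), tolerance = 1e-12)
  expect_equal(idn$translation, c(0, 0, 0), tolerance = 1e-12)

  dbl <- landmark_similarity(X, 2 * X)
  expect_equal(dbl$scale, 2, tolerance = 1e-12)
  expect_equal(dbl$rotation, diag(3), tolerance = 1e-12)
  expect_equal(dbl$translation, c(0, 0, 0), tolerance = 1e-10)

  for (rep in 1:5) {
    truth <- random_similarity()
    Y <- apply_transform(X, truth)
    est <- landmark_similarity(X, Y)
    expect_equal(est$scale, truth$scale, tolerance = 1e-8)
    expect_lt(max(abs(est$rotation - truth$rotation)), 1e-8)
    expect_lt(max(abs(est$translation - truth$translation)), 1e-8)
    expect_lt(attr(est, "rms"), 1e-10)
  }
})

test_that("closed-form similarity matches a numeric optimiser on small instances", {
  # oracle: direct minimisation over axis-angle rotation + scale + translation
  sse_for <- function(par, X, Y) {
    ang <- sqrt(sum(par[1:3]^2))
    axis <- if (ang > 0) par[1:3] / ang else c(1, 0, 0)
    K <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
               c(-axis[2], axis[1], 0))
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    s <- exp(par[4])
    t <- par[5:7]
    sum((sweep(X %*% t(R) * s, 2, t, "+") - Y)^2)
  }
  set.seed(17)
  for (rep in 1:4) {
    k <- sample(4:6, 1)
    X <- matrix(rnorm(3 * k), ncol = 3)
    Y <- apply_transform(X, random_similarity()) +
      matrix(rnorm(3 * k, sd = 0.05), ncol = 3)
    est <- landmark_similarity(X, Y)
    sse_closed <- sum((apply_transform(X, est) - Y)^2)
    best <- Inf
    for (start in 1:4) {
      par0 <- c(rnorm(3, sd = 0.5), 0, rnorm(3, sd = 0.5))
      opt <- optim(par0, sse_for, X = X, Y = Y, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
      best <- min(best, opt$value)
    }
    expect_lte(sse_closed, best + 1e-6)
  }
})

test_that("degenerate and rigid-only cases are handled", {
  line <- cbind(1:5, 0, 0)
  expect_error(landmark_similarity(line, line), "collinear")
  expect_error(landmark_similarity(diag(3)[1:2, ], diag(3)[1:2, ]),
               "at least 3")
  set.seed(8)
  X <- matrix(rnorm(12), ncol = 3)
  Y <- apply_transform(X, similarity_transform(3, euler_rotation(0.4)))
  rigid <- landmark_similarity(X, Y, with_scale = FALSE)
  expect_identical(rigid$scale, 1)
})

test_that("ICP on an exact copy converges immediately to identity", {
  m <- make_claw(claw_params(n_axial = 12L, n_radial = 10L))
  res <- icp_align(m, m)
  expect_lte(res$iterations_run, 2L)
  expect_lt(res$rms_history[length(res$rms_history)], 1e-10)
  expect_equal(res$transform$scale, 1, tolerance = 1e-9)
  expect_lt(max(abs(res$transform$rotation - diag(3))), 1e-9)
  expect_true(res$converged)
})

test_that("ICP default budget is 20 iterations and history honours it", {
  expect_identical(eval(formals(icp_align)$max_iterations), 20L)
  m <- make_claw(claw_params(n_axial = 12L, n_radial = 10L))
  noisy <- m
  set.seed(2)
  noisy$vertices <- noisy$vertices + matrix(rnorm(3 * n_vertices(m),
                                                  sd = 0.05), ncol = 3)
  res <- icp_align(noisy, m, rel_rms_tolerance = 0)
  expect_identical(res$iterations_run, 20L)
  expect_length(res$rms_history, 20L)
})

test_that("landmark-seeded ICP recovers a planted similarity on a noiseless claw", {
  m <- make_claw()
  dg <- degrade(m, degradation_spec(distal_fraction = 0.3,
                                    hole_radius = 0.6))$mesh
  pl <- plant_transform(dg, scale = 0.8, rotation = c(10, -6, 8) * pi / 180,
                        translation = c(2, -1, 0.5))
  lp <- make_landmark_pair(pl$mesh, dg, c(5L, 120L, 260L, 400L))
  init <- landmark_similarity(lp$a, lp$b)
  res <- icp_align(pl$mesh, m, initial = init)
  expect_lt(res$rms_history[length(res$rms_history)], 1e-6)
  expect_equal(res$transform$scale, pl$truth$scale, tolerance = 1e-4)
  expect_lt(max(abs(res$transform$rotation - pl$truth$rotation)), 1e-4)
})

test_that("the RMS objective is non-increasing on random perturbed pairs", {
  set.seed(23)
  for (rep in 1:10) {
    ref <- matrix(rnorm(300 * 3), ncol = 3)
    src <- apply_transform(ref, moderate_similarity()) +
      matrix(rnorm(300 * 3, sd = 0.02), ncol = 3)
    res <- icp_align(src, ref, max_iterations = 12L)
    expect_true(all(diff(res$rms_history) <= 1e-9))
  }
  # wildly mis-posed scaled ICP can collapse; that is a typed numeric error
  set.seed(24)
  degenerate_seen <- FALSE
  for (rep in 1:20) {
    ref <- matrix(rnorm(120 * 3), ncol = 3)
    src <- apply_transform(ref, random_similarity()) +
      matrix(rnorm(120 * 3, sd = 0.02), ncol = 3)
    out <- tryCatch(icp_align(src, ref, max_iterations = 10L),
                    error = function(e) e)
    if (inherits(out, "error")) {
      degenerate_seen <- TRUE
      expect_match(conditionMessage(out), "degenerate|non-finite")
    } else {
      expect_true(all(diff(out$rms_history) <= 1e-9))
    }
  }
})

test_that("registration is invariant to a common rigid motion of both inputs", {
  m <- make_claw(claw_params(n_axial = 16L, n_radial = 12L))
  src <- m
  set.seed(4)
  src$vertices <- src$vertices + matrix(rnorm(3 * n_vertices(m), sd = 0.03),
                                        ncol = 3)
  base <- icp_align(src, m)
  motion <- similarity_transform(1, euler_rotation(0.7, -0.3, 0.2),
                                 c(5, -3, 2))
  moved <- icp_align(apply_transform(src, motion), apply_transform(m, motion))
  expect_equal(base$rms_history[length(base$rms_history)],
               moved$rms_history[length(moved$rms_history)],
               tolerance = 1e-8)
})

test_that("transforms compose, invert, and apply as a group action", {
  set.seed(31)
  pts <- matrix(rnorm(60), ncol = 3)
  expect_identical(apply_transform(pts, similarity_transform()), pts)
  for (rep in 1:5) {
    t1 <- random_similarity()
    t2 <- random_similarity()
    two_step <- apply_transform(apply_transform(pts, t1), t2)
    composed <- apply_transform(pts, compose_transforms(t2, t1))
    expect_lt(max(abs(two_step - composed)), 1e-10)
    round_trip <- apply_transform(apply_transform(pts, t1),
                                  invert_transform(t1))
    expect_lt(max(abs(round_trip - pts)), 1e-10)
  }
})

test_that("iteration sweep returns the default budget grid with a plateau", {
  m <- make_claw(claw_params(n_axial = 16L, n_radial = 12L))
  dg <- degrade(m, degradation_spec(distal_fraction = 0.25))$mesh
  pl <- plant_transform(dg, scale = 1.2, rotation = c(0.1, 0.05, -0.1),
                        translation = c(1, 0, -1))
  lp <- make_landmark_pair(pl$mesh, dg, c(3L, 50L, 95L, 140L))
  sw <- iteration_sweep(pl$mesh, m,
                        initial = landmark_similarity(lp$a, lp$b))
  expect_equal(sw$budget, seq(5L, 100L, by = 5L))
  expect_equal(nrow(sw), 20L)
  expect_true(all(diff(sw$rms) <= 1e-12))
  plateau <- attr(sw, "plateau_budget")
  expect_false(is.na(plateau))
  expect_lt(plateau, 100L)
  expect_lt(sw$rms[nrow(sw)], 1e-6)
})
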