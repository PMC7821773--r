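test_that("trial tables validate, assemble from records, and round-trip CSV", {
  tab <- ungual_trials()
  expect_s3_class(tab, "trial_table")
  expect_equal(nrow(tab), 12L)
  expect_equal(levels(tab$reference), c("MCI", "MCII"))
  expect_equal(sum(tab$n_points), 4L * (34928L + 14050L + 12780L))

  recs <- lapply(seq_len(12L), function(i) {
    list(removal = as.character(tab$removal[i]),
         method = as.character(tab$method[i]),
         icp = as.character(tab$icp[i]),
         reference = as.character(tab$reference[i]),
         mean_distance = tab$mean_distance[i],
         sd_distance = tab$sd_distance[i], n_points = tab$n_points[i])
  })
  built <- build_trial_table(recs)
  expect_equal(built$mean_distance, tab$mean_distance)

  expect_error(build_trial_table(recs[1L]), "at least 2")
  bad <- recs
  bad[[1L]]$icp <- NULL
  expect_error(build_trial_table(bad), "missing factor value 'icp'")
  expect_warning(build_trial_table(c(recs, recs[1L])), "duplicate")

  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(tab, path)
  back <- read_trial_table(path)
  expect_equal(back$mean_distance, tab$mean_distance)
  expect_equal(as.character(back$reference), as.character(tab$reference))
})

test_that("records carrying field summaries feed the trial table directly", {
  m <- make_claw(claw_params(n_axial = 10L, n_radial = 8L))
  cmp <- pairwise_compare(m, m, mode = "c2c", icp = FALSE)
  recs <- list(
    list(removal = "no", method = "C2C", icp = "no", reference = "A",
         summary = cmp$summary),
    list(removal = "no", method = "C2C", icp = "yes", reference = "B",
         mean_distance = 0.5)
  )
  tab <- build_trial_table(recs)
  expect_equal(tab$n_points[1L], n_vertices(m))
  expect_equal(tab$mean_distance[1L], 0)
})

test_that("type-II decomposition matches the independent car::Anova oracle", {
  skip_if_not_installed("car")
  tab <- ungual_trials()
  fit <- anova_type2(tab, n_permutations = 0L)
  lmfit <- stats::lm(mean_distance ~ removal + method + icp + reference,
                     data = tab)
  oracle <- car::Anova(lmfit, type = 2)
  for (f in c("removal", "method", "icp", "reference")) {
    expect_equal(fit[f, "SS"], oracle[f, "Sum Sq"], tolerance = 1e-10)
    expect_equal(fit[f, "F"], oracle[f, "F value"], tolerance = 1e-10)
  }
  expect_equal(fit["Residuals", "SS"], oracle["Residuals", "Sum Sq"],
               tolerance = 1e-10)
})

test_that("ANOVA bookkeeping invariants hold on the trial data", {
  tab <- ungual_trials()
  fit <- anova_type2(tab, seed = 5L)
  expect_equal(fit["Total", "Df"], 11L)
  expect_equal(sum(fit[c("removal", "method", "icp", "reference",
                         "Residuals"), "Df"]), fit["Total", "Df"])
  expect_equal(fit["Total", "SS"],
               sum((tab$mean_distance - mean(tab$mean_distance))^2),
               tolerance = 1e-12)
  expect_true(all(fit$SS >= 0))
  expect_equal(fit$R2, fit$SS / fit["Total", "SS"], tolerance = 1e-12)
  terms <- c("removal", "method", "icp", "reference")
  expect_equal(fit[terms, "F"],
               fit[terms, "MS"] / fit["Residuals", "MS"],
               tolerance = 1e-12)
})

test_that("balanced one-way SS matches the closed-form between-group formula", {
  y <- c(1.2, 0.9, 1.1, 1.0, 2.3, 2.1, 2.4, 2.2)
  g <- rep(c("a", "b"), each = 4L)
  tab <- data.frame(group = g, y = y)
  fit <- anova_type2(tab, response = "y", factors = "group",
                     n_permutations = 99L, seed = 2L)
  closed <- (4 * 4 / 8) * (mean(y[1:4]) - mean(y[5:8]))^2
  expect_equal(fit["group", "SS"], closed, tolerance = 1e-12)
  # single balanced factor: type II equals sequential SS from stats::anova
  seq_ss <- stats::anova(stats::lm(y ~ group, tab))["group", "Sum Sq"]
  expect_equal(fit["group", "SS"], seq_ss, tolerance = 1e-12)
})

test_that("permutation p-values respect the floor and the seed contract", {
  tab <- ungual_trials()
  B <- 199L
  f1 <- anova_type2(tab, n_permutations = B, seed = 42L)
  f2 <- anova_type2(tab, n_permutations = B, seed = 42L)
  expect_identical(f1$p, f2$p)
  expect_identical(f1$Z, f2$Z)
  terms <- c("removal", "method", "icp", "reference")
  expect_true(all(f1[terms, "p"] >= 1 / (B + 1)))
  expect_true(all(f1[terms, "p"] <= 1))
  f3 <- anova_type2(tab, n_permutations = B, seed = 43L)
  expect_false(identical(f1$p, f3$p))
})

test_that("degenerate responses and aliased factors are flagged", {
  tab <- data.frame(a = rep(c("x", "y"), 4L), b = rep(c("u", "v"), each = 4L),
                    y = rep(1, 8L))
  fit <- anova_type2(tab, response = "y", factors = c("a", "b"),
                     n_permutations = 9L, seed = 1L)
  expect_true(all(fit[c("a", "b"), "SS"] == 0))
  expect_true(all(is.na(fit[c("a", "b"), "F"])))

  # a factor perfectly aliased with another has no df after adjustment
  tab2 <- data.frame(a = rep(c("x", "y"), 4L), a2 = rep(c("p", "q"), 4L),
                     y = rnorm(8L))
  expect_error(anova_type2(tab2, response = "y", factors = c("a", "a2"),
                           n_permutations = 0L),
               "aliased")
  expect_error(anova_type2(data.frame(a = rep("x", 5L), y = rnorm(5L)),
                           response = "y", factors = "a"),
               "fewer than 2 levels")
})

test_that("a planted dominant factor wins the R2 ranking almost always", {
  wins <- 0L
  n_rep <- 200L
  set.seed(77)
  for (r in seq_len(n_rep)) {
    n <- 16L
    f1 <- rep(c("a", "b"), each = n / 2)           # planted: big effect
    f2 <- rep(c("u", "v"), times = n / 2)          # noise only
    f3 <- sample(rep(c("p", "q"), times = n / 2))  # noise only
    y <- ifelse(f1 == "a", 0, 2) + rnorm(n, sd = 0.8)
    tab <- data.frame(f1 = f1, f2 = f2, f3 = f3, y = y)
    fit <- anova_type2(tab, response = "y", factors = c("f1", "f2", "f3"),
                       n_permutations = 0L)
    r2 <- fit[c("f1", "f2", "f3"), "R2"]
    if (which.max(r2) == 1L) wins <- wins + 1L
  }
  expect_gte(wins, 0.95 * n_rep)
})
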