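# Logistic fitting, blank correction, carbon profiles and the Euclidean
# dissimilarity derived from them.

test_that("blank correction subtracts pointwise and clips at zero", {
  cu <- growth_curve(c(0, 1), c(0.1, 0.5))
  bl <- growth_curve(c(0, 1), c(0.05, 0.05))
  expect_equal(blank_correct(cu, bl)$values, c(0.05, 0.45))
  expect_true(blank_correct(cu, bl)$blank_corrected)

  # curve equal to its blank vanishes
  expect_equal(blank_correct(cu, cu)$values, c(0, 0))

  # blank exceeding the curve clips that point to zero
  bl2 <- growth_curve(c(0, 1), c(0.2, 0.05))
  expect_equal(blank_correct(cu, bl2)$values, c(0, 0.45))

  # blank on a different grid is interpolated; disjoint ranges refuse
  bl3 <- growth_curve(c(-1, 2), c(0.05, 0.05))
  expect_equal(blank_correct(cu, bl3)$values, c(0.05, 0.45))
  bl4 <- growth_curve(c(5, 6), c(0, 0))
  expect_error(blank_correct(cu, bl4), "cover")
})

test_that("noiseless logistic curves are recovered exactly over a parameter grid", {
  for (mu in c(0.1, 0.5, 1)) {
    for (K in c(0.5, 1, 2)) {
      tt <- seq(0, ceiling(1.5 * log(99) / mu), length.out = 25)
      fit <- fit_logistic(sim_logistic_curve(mu, K, K / 100, tt))
      expect_lt(abs(fit$mu - mu), 1e-6)
      expect_lt(abs(fit$K - K), 1e-6)
      expect_true(fit$converged)
    }
  }
})

test_that("analytic AUC agrees with trapezoid integration of the fitted curve", {
  fit <- fit_logistic(sim_logistic_curve(0.5, 1, 0.01, seq(0, 48, by = 2)))
  tt <- seq(min(fit$times), max(fit$times), length.out = 2000)
  yy <- predict(fit, tt)
  trap <- sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
  expect_lt(abs(fit$auc - trap) / trap, 0.001)
})

test_that("degenerate curves yield the no-growth fit, not an exception", {
  flat <- growth_curve(0:9, rep(0, 10))
  fit <- fit_logistic(flat)
  expect_false(fit$converged)
  expect_equal(fit$mu, 0)
  expect_equal(fit$K, 0)
  expect_error(fit_logistic(growth_curve(0:2, c(0, 0.1, 0.2))), "4 points")
})

test_that("mu is recovered within 10% for most noisy curves", {
  hits <- 0
  for (i in 1:100) {
    cu <- sim_logistic_curve(0.5, 1, 0.01, seq(0, 48, length.out = 25),
                             noise_cv = 0.05, seed = 4000 + i)
    f <- fit_logistic(cu)
    if (abs(f$mu / 0.5 - 1) < 0.1) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("carbon profiles are z-scored per column with sample SD", {
  fits <- data.frame(strain = rep(c("s1", "s2"), each = 2),
                     carbon = rep(c("glc", "fru"), 2),
                     mu = c(0.5, 0.4, 0.5, 0.2),
                     K = c(1, 0, 1, 0.5))
  expect_warning(prof <- build_carbon_profile(fits), "zero-variance")
  # two-strain contrast: z-scores are +-1/sqrt(2) under sample SD
  expect_equal(unname(prof[, "fru_K"]), c(-1, 1) / sqrt(2))
  expect_true(all(abs(colMeans(prof)) < 1e-12))
  expect_true(all(abs(apply(prof, 2, sd) - 1) < 1e-12))
  expect_error(build_carbon_profile(fits[fits$strain == "s1", ]), "2 strains")
})

test_that("non-converged fits are coded as no growth before scaling", {
  fits <- data.frame(strain = rep(c("s1", "s2"), each = 1),
                     carbon = "glc",
                     mu = c(0.5, 0.9), K = c(1, 2),
                     converged = c(TRUE, FALSE))
  prof <- build_carbon_profile(fits)
  # s2 was forced to (0, 0): s1 must sit above s2 in both columns
  expect_true(all(prof["s1", ] > prof["s2", ]))
})

test_that("profile dissimilarity is a Euclidean metric with a merge tree", {
  m <- matrix(c(0, 0, 3, 4, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("x", "y")))
  class(m) <- c("carbon_profile", "matrix", "array")
  d <- profile_dissimilarity(m, "a")
  expect_equal(unname(d$entries["b"]), 5)      # 3-4-5 triangle
  expect_equal(unname(d$entries["c"]), 0)      # identical rows
  expect_equal(d$dist_matrix["a", "a"], 0)
  expect_error(profile_dissimilarity(m, "zz"), "absent")

  # metric properties on random z-scored matrices
  set.seed(1)
  for (rep in 1:5) {
    M <- matrix(rnorm(6 * 4), 6, 4,
                dimnames = list(paste0("s", 1:6), paste0("v", 1:4)))
    dm <- profile_dissimilarity(structure(M, class = c("carbon_profile", "matrix", "array")), "s1")$dist_matrix
    expect_equal(dm, t(dm))
    expect_true(all(diag(dm) == 0))
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
  }
})

test_that("complete-linkage clustering groups planted profile clusters", {
  # two planted clusters of strains with distinct mu/K signatures
  set.seed(7)
  strains <- paste0("s", 1:7)
  cluster_of <- c(1, 1, 1, 1, 2, 2, 2)
  fits <- do.call(rbind, lapply(1:7, function(i) {
    base_mu <- if (cluster_of[i] == 1) c(0.6, 0.5, 0) else c(0, 0.1, 0.7)
    base_K <- if (cluster_of[i] == 1) c(1.2, 1.0, 0) else c(0, 0.2, 1.5)
    data.frame(strain = strains[i], carbon = c("glc", "fru", "mal"),
               mu = base_mu + rnorm(3, 0, 0.02),
               K = base_K + rnorm(3, 0, 0.02))
  }))
  prof <- build_carbon_profile(fits)
  hc <- profile_dissimilarity(prof, "s1")$hclust
  groups <- cutree(hc, k = 2)
  expect_equal(length(unique(groups[cluster_of == 1])), 1)
  expect_equal(length(unique(groups[cluster_of == 2])), 1)
  expect_false(groups[1] == groups[7])
})

test_that("plate-reader tables round trip through CSV", {
  curves <- list(A1 = sim_logistic_curve(0.5, 1, 0.01, seq(0, 24, by = 2)),
                 A2 = sim_logistic_curve(0.3, 0.8, 0.01, seq(0, 24, by = 2)))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_growth_table(curves, path, strain = c("sp1", "sp2"),
                     condition = "glucose")
  back <- read_growth_table(path)
  expect_equal(back$A1$values, curves$A1$values)
  expect_equal(back$A2$times, curves$A2$times)
  expect_equal(back$A1$label, "sp1 x glucose")
})
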