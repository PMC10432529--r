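# The fluorescence-dilution single-cell chain: background correction, RS,
# LOD, binning, founder reconstruction, Bray-Curtis and PERMANOVA.

test_that("background correction is per field of view with a positive floor", {
  cells <- data.frame(cell_id = 1:4,
                      fov = c("f1", "f1", "f2", "f2"),
                      green = c(500, 150, 500, 90),
                      bg_green = c(100, 100, 90, 90))
  out <- background_correct(cells)
  expect_equal(out$green_corrected, c(400, 50, 410, 1))
  expect_equal(out$bg_flagged, c(FALSE, FALSE, FALSE, TRUE))

  # FOVs are corrected independently even with unequal backgrounds
  cells2 <- cells; cells2$bg_green <- c(100, 100, 400, 400)
  out2 <- background_correct(cells2)
  expect_equal(out2$green_corrected[3], 100)
  expect_true(out2$bg_flagged[4])

  cells$bg_green[3] <- NA
  expect_error(background_correct(cells), "background")
})

test_that("reproductive success is the log2 intensity ratio", {
  expect_equal(reproductive_success(1000, 1000), 0)
  expect_equal(reproductive_success(1000, 250), 2)
  expect_equal(reproductive_success(1000, 1000 / 32), 5)
  expect_equal(reproductive_success(1000, c(500, 125)), c(1, 3))
  expect_error(reproductive_success(0, 10), "positive")
  expect_error(reproductive_success(10, c(1, -2)), "positive")
})

test_that("LOD is the alpha-quantile of background RS, snapped to a bin edge", {
  # uniform grid on [4, 6]: the 5% quantile interpolates to 4.1
  bg <- seq(4, 6, length.out = 41)
  r <- lod_from_background(bg)
  expect_equal(r$lod, 4.1)
  expect_equal(r$working_lod, 3.5)
  expect_equal(r$lod, oracle_quantile(bg, 0.05))

  # constant background: quantile equals that constant
  expect_equal(lod_from_background(rep(5, 30))$lod, 5)

  # a 4.58 quantile works out to the 4.5 bin edge
  grid <- seq(4.08, 14.08, length.out = 101)
  r2 <- lod_from_background(grid)
  expect_equal(r2$lod, 4.58)
  expect_equal(r2$working_lod, 4.5)

  expect_error(lod_from_background(rep(5, 10)), "at least 20")
})

test_that("binning follows the printed half-open edges with LOD censoring", {
  rs <- c(-0.2, 0.49, 0.5, 1.49, 1.5, 2.49, 3.5, 4.49, 4.5, 7.2)
  rec <- bin_rs(rs)
  expect_equal(as.character(rec$bin),
               c("RS_0", "RS_0", "RS_1", "RS_1", "RS_2", "RS_2", "RS_4",
                 "RS_4", "RS_>4", "RS_>4"))
  expect_equal(rec$censored, rs >= 4.5)
  expect_equal(attr(rec, "n_negative"), 1L)
  expect_error(bin_rs(rs, lod = 4.2), "bin edge")
  # a lower working LOD pools earlier
  rec2 <- bin_rs(c(3.4, 3.6), lod = 3.5)
  expect_equal(as.character(rec2$bin), c("RS_3", "RS_>4"))
  expect_true(rec2$censored[2])
})

test_that("RS distributions are unit-sum fractions per experimental unit", {
  rec <- bin_rs(c(0.1, 0.2, 1.1, 2.1, 2.2, 5.0))
  groups <- data.frame(treatment = c("a", "a", "a", "b", "b", "b"),
                       timepoint = c(0, 0, 0, 24, 24, 24))
  expect_warning(d <- rs_distribution(rec, groups), "fewer than 100")
  expect_equal(nrow(d), 2)
  fr <- as.matrix(d[, phyllocomp:::RS_BINS])
  expect_equal(unname(rowSums(fr)), c(1, 1))
  expect_equal(d$n_cells, c(3L, 3L))
  a <- d[d$treatment == "a", ]
  expect_equal(a$RS_0, 2 / 3)
  expect_equal(a$RS_1, 1 / 3)
})

test_that("founder reconstruction inverts descendant weighting", {
  # all founders divided twice
  r <- founder_reconstruction(c(RS_2 = 1))
  expect_equal(unname(r$founder_fractions), 1)
  expect_equal(r$fold_increase, 4)

  # worked mixture, against explicit founder bookkeeping
  r2 <- founder_reconstruction(c(RS_0 = 0.5, RS_1 = 0.5))
  expect_equal(unname(r2$founder_fractions), c(2 / 3, 1 / 3))
  expect_equal(r2$fold_increase, 4 / 3)
  # oracle: two founders at k=0 and one at k=1 yield cells (2 + 2) with
  # observed fractions (0.5, 0.5), founder fractions (2/3, 1/3), fold 4/3
  oracle <- oracle_founder_reconstruction(c(0, 0, 1))
  expect_equal(oracle$cell_fractions, c(0.5, 0.5))
  expect_equal(unname(r2$founder_fractions), oracle$founder_fractions)
  expect_equal(r2$fold_increase, oracle$fold_increase)

  # no divisions, no growth
  expect_equal(founder_reconstruction(c(RS_0 = 1))$fold_increase, 1)
  expect_error(founder_reconstruction(numeric(0)), "empty")
})

test_that("the noise-free chain recovers planted founder structure exactly", {
  pmf <- c(0.25, 0.3, 0.2, 0.15, 0.1)   # divisions 0..4
  pop <- sim_cusper_population(400, pmf, gfp_mean = 4000, gfp_cv = 0, seed = 21)
  rs <- reproductive_success(4000, pop$cells$green)
  rec <- bin_rs(rs)
  f <- as.numeric(table(rec$bin)) / nrow(rec)
  names(f) <- levels(rec$bin)
  r <- founder_reconstruction(f)
  planted <- table(factor(pop$truth$founder_divisions, levels = 0:4)) / 400
  expect_equal(unname(r$founder_fractions[1:5]), as.numeric(planted))
  expect_equal(r$fold_increase, mean(2^pop$truth$founder_divisions))
})

test_that("planted divisions past the LOD always land censored when noise-free", {
  pop <- sim_cusper_population(50, c(rep(0, 5), 0.5, 0, 0.5), gfp_cv = 0,
                               seed = 5)  # divisions 5 or 7
  rs <- reproductive_success(pop$truth$gfp_mean, pop$cells$green)
  rec <- bin_rs(rs)
  expect_true(all(rec$censored))
  expect_true(all(rec$bin == "RS_>4"))
})

test_that("Bray-Curtis matches the hand formula and its boundary cases", {
  m <- rbind(c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0.5, 0.5, 0), c(0, 0, 1))
  bc <- bray_curtis(m)
  expect_equal(bc[1, 2], 0.5)
  expect_equal(bc[1, 3], 0)            # identical rows
  expect_equal(bc[2, 4], 0.5)
  expect_equal(bc[1, 4], 1)            # disjoint supports
  expect_equal(bc, t(bc))
  set.seed(3)
  r <- matrix(rgamma(5 * 4, 1), 5); r <- r / rowSums(r)
  bcr <- bray_curtis(r)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(bcr[i, j], oracle_bray_curtis(r[i, ], r[j, ]))
  expect_error(bray_curtis(rbind(c(-0.1, 1.1), c(0.5, 0.5))), "non-negative")
  expect_error(bray_curtis(rbind(c(0.2, 0.2), c(0.5, 0.5))), "sum to 1")
})

test_that("PERMANOVA reproduces the reference decomposition", {
  set.seed(11)
  m <- matrix(rgamma(18 * 6, 2), 18); m <- m / rowSums(m)
  fac <- data.frame(time = rep(c("t0", "t24", "t36"), each = 6),
                    treatment = rep(c("mono", "comp"), 9))
  D <- bray_curtis(m)
  mine <- permanova(D, fac, n_perm = 299, seed = 4)
  ref <- vegan::adonis2(as.dist(D) ~ time + treatment, data = fac,
                        permutations = 299, by = "terms")
  expect_equal(mine$ss[1:2], ref$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(mine$r_squared[1:2], ref$R2[1:2], tolerance = 1e-10)
  expect_equal(mine$pseudo_F[1:2], ref$F[1:2], tolerance = 1e-10)
  expect_equal(mine$df, c(2L, 1L, 14L))
  # permutation p-values from independent streams agree within Monte Carlo error
  expect_lt(max(abs(mine$p_value[1:2] - ref$`Pr(>F)`[1:2])), 0.15)
  # p resolution is 1/(n_perm + 1)
  expect_true(all(mine$p_value[1:2] >= 1 / 300))
})

test_that("PERMANOVA handles degenerate and invalid designs", {
  m <- matrix(rep(c(0.5, 0.3, 0.2), each = 8), 8)
  m <- m / rowSums(m)
  D <- bray_curtis(m)
  fac <- data.frame(g = rep(c("a", "b"), each = 4))
  res <- permanova(D, fac, n_perm = 99, seed = 1)
  expect_equal(res$pseudo_F[1], 0)
  expect_equal(res$p_value[1], 1)
  expect_error(permanova(D, data.frame(g = rep("a", 8)), n_perm = 9),
               "fewer than 2 groups")
  expect_error(permanova(D[1:3, 1:3], data.frame(g = c("a", "b", "c")),
                         n_perm = 9), "singleton|residual")
})

test_that("permutation stream is reproducible under a seed", {
  set.seed(99)
  m <- matrix(rgamma(12 * 5, 2), 12); m <- m / rowSums(m)
  fac <- data.frame(g = rep(c("a", "b"), each = 6))
  D <- bray_curtis(m)
  r1 <- permanova(D, fac, n_perm = 199, seed = 8)
  r2 <- permanova(D, fac, n_perm = 199, seed = 8)
  expect_identical(r1, r2)
})
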