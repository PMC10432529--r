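# FBA, minimal-media enumeration, the MRO index and model I/O.

INORG3 <- c("nh4", "pi", "so4")

test_that("media presets carry the documented carbon compositions", {
  m5 <- media_presets("M5C")
  expect_setequal(m5$carbon_sources,
                  c("glucose", "fructose", "malate", "sorbitol", "methanol"))
  l10 <- media_presets("L10C")
  expect_length(l10$carbon_sources, 10)
  expect_setequal(l10$carbon_sources,
                  c("fumarate", "sucrose", "aspartate", "malate", "citrate",
                    "glutamate", "alanine", "fructose", "threonine",
                    "methanol"))
  l8 <- media_presets("L8C")
  expect_length(l8$carbon_sources, 8)
  expect_true("glucose" %in% l8$carbon_sources)
  expect_false(any(c("citrate", "alanine", "threonine") %in% l8$carbon_sources))
  expect_setequal(setdiff(l8$carbon_sources, "glucose"),
                  setdiff(l10$carbon_sources,
                          c("citrate", "alanine", "threonine")))
  expect_error(media_presets("L13C"), "user medium_spec")
  expect_error(medium_spec("bad", "glucose", c("glucose", "nh4")), "disjoint")
})

test_that("models round trip through the JSON dialect and SBML", {
  mods <- toy_models(list(A = c("glucose", "fructose")), inorganic_set = INORG3)
  med <- medium_spec("t", c("glucose", "fructose"), INORG3)
  ref <- fba(mods$A, med)

  jp <- tempfile(fileext = ".json"); sp <- tempfile(fileext = ".xml")
  on.exit(unlink(c(jp, sp)))
  write_model_json(mods$A, jp)
  write_model_sbml(mods$A, sp)
  mj <- load_model(jp)
  ms <- load_model(sp)
  expect_equal(length(mj$reactions), length(mods$A$reactions))
  expect_equal(length(ms$reactions), length(mods$A$reactions))
  expect_equal(fba(mj, med), ref, tolerance = 1e-9)
  expect_equal(fba(ms, med), ref, tolerance = 1e-9)
  expect_equal(sort(model_compounds(ms)), sort(model_compounds(mods$A)))

  # SBML with no recognisable biomass reaction is rejected
  txt <- readLines(sp)
  txt <- gsub("(?i)biomass", "growthrxn", txt, perl = TRUE)
  txt <- txt[!grepl("Objective", txt)]
  writeLines(txt, sp)
  expect_error(read_model_sbml(sp), "biomass")
})

test_that("FBA respects medium composition and scales linearly in the uptake cap", {
  mods <- toy_models(list(A = "glucose"), inorganic_set = INORG3)
  m5 <- media_presets("M5C", inorganics = INORG3)
  expect_gt(fba(mods$A, m5), 0)
  none <- medium_spec("none", "fumarate", INORG3)
  expect_equal(fba(mods$A, none), 0)

  v1 <- fba(mods$A, medium_spec("u1", "glucose", INORG3, uptake_bound = 5))
  v2 <- fba(mods$A, medium_spec("u2", "glucose", INORG3, uptake_bound = 10))
  expect_equal(v2, 2 * v1, tolerance = 1e-9)
})

test_that("removing medium compounds never increases the FBA optimum", {
  cfg <- random_toy_config(101, n_species = 1, n_carbons = 4)
  model <- cfg$models[[1]]
  full <- fba(model, cfg$medium)
  for (m in medium_compounds(cfg$medium)) {
    reduced <- phyllocomp:::fba_subset(
      model, cfg$medium, setdiff(medium_compounds(cfg$medium), m))
    expect_lte(reduced, full + 1e-9)
  }
})

test_that("minimal-media enumeration equals exhaustive subset search", {
  for (seed in c(1, 2, 3)) {
    cfg <- random_toy_config(seed, n_species = 2, n_carbons = 4)
    for (model in cfg$models) {
      res <- minimal_media(model, cfg$medium)
      oracle <- oracle_minimal_media(model, cfg$medium)
      expect_true(same_set_collection(res$minimal_sets, oracle),
                  label = paste("seed", seed, "model", model$id))
    }
  }
  # the documented two-alternative case
  mods <- toy_models(list(B = c("glucose", "fructose")), inorganic_set = INORG3,
                     extra_carbons = "sorbitol")
  med <- medium_spec("t", c("glucose", "fructose", "sorbitol"), INORG3)
  res <- minimal_media(mods$B, med)
  expect_length(res$minimal_sets, 2)
  expect_setequal(intersect(res$union_requirements, med$carbon_sources),
                  c("glucose", "fructose"))
  expect_error(minimal_media(mods$B, med, threshold_fraction = 1.5),
               "threshold")
})

test_that("unusable carbon sources never enter minimal media", {
  mods <- toy_models(list(A = "glucose"), inorganic_set = INORG3,
                     extra_carbons = c("fructose", "sorbitol"))
  med_small <- medium_spec("s", "glucose", INORG3)
  med_big <- medium_spec("b", c("glucose", "fructose", "sorbitol"), INORG3)
  r1 <- minimal_media(mods$A, med_small)
  r2 <- minimal_media(mods$A, med_big)
  expect_true(same_set_collection(r1$minimal_sets, r2$minimal_sets))
})

test_that("MRO is a symmetric overlap index on [0, 1]", {
  mods <- toy_models(list(A = c("glucose", "fructose"), B = "glucose",
                          C = "sorbitol"),
                     inorganic_set = c("nh4", "pi"))
  med <- medium_spec("t", c("glucose", "fructose", "sorbitol"), c("nh4", "pi"))
  rA <- minimal_media(mods$A, med)
  rB <- minimal_media(mods$B, med)
  rC <- minimal_media(mods$C, med)

  # identity: |M_A| = 4 ({glc, fru, nh4, pi}), overlap with itself is 1
  expect_equal(mro(rA, rA, medium = med)$mro, 1)

  # documented set arithmetic: {glc, fru, nh4, pi} vs {glc, nh4, pi}
  r <- mro(rA, rB, medium = med)
  expect_equal(r$mro, 3 / 3.5)
  expect_equal(unname(r$set_sizes), c(4, 3, 3))
  expect_equal(mro(rA, rB, medium = med, normalisation = "min")$mro, 1)

  # symmetry
  expect_equal(mro(rB, rA, medium = med)$mro, r$mro)

  # disjoint carbon utilisers have zero carbon-restricted overlap
  expect_equal(mro(rB, rC, medium = med, carbon_only = TRUE)$mro, 0)

  # mismatched media refuse
  med2 <- medium_spec("other", c("glucose", "fructose", "sorbitol"),
                      c("nh4", "pi"))
  rB2 <- minimal_media(mods$B, med2)
  expect_error(mro(rA, rB2), "different media")
})
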