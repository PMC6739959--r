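test_that("templates have the documented landmark economy", {
  h <- makeTemplate("humerus36")
  expect_equal(nrow(h$template), 36L)
  expect_equal(nrow(h$sliders), 14L)
  expect_length(h$fixed, 22L)
  m <- makeTemplate("mandible38")
  expect_equal(nrow(m$template), 38L)
  expect_equal(nrow(m$sliders), 26L)
  expect_length(m$fixed, 12L)
  for (tpl in list(h, m)) {
    expect_equal(centroidSize(tpl$template), 1, tolerance = 1e-12)
    expect_silent(validateSliderTable(tpl$sliders, k = nrow(tpl$template)))
    # outline adjacency: neighbours are the adjacent outline points
    k <- nrow(tpl$template)
    expect_true(all(tpl$sliders$before ==
                    ifelse(tpl$sliders$slider == 1, k, tpl$sliders$slider - 1)))
    expect_true(all(tpl$sliders$after ==
                    ifelse(tpl$sliders$slider == k, 1, tpl$sliders$slider + 1)))
  }
})

test_that("simulated trees are deterministic, unit-depth and labelled", {
  t1 <- simulateTree(10, seed = 5)
  t2 <- simulateTree(10, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(max(ape::node.depth.edgelength(t1)), 1, tolerance = 1e-12)
  expect_identical(t1$tip.label, sprintf("sp%03d", 1:10))
  t3 <- simulateTree(10, seed = 6)
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
})

test_that("generator configuration is validated", {
  expect_error(generatorConfig(integrationRho = 1.5))
  expect_error(generatorConfig(integrationRho = c(a = 0.5, b = 0.5)), "named")
  expect_error(generatorConfig(disparityRatio = 0))
  expect_error(generatorConfig(groupFraction = 1))
  cfg <- generatorConfig(integrationRho = 0.7)
  expect_equal(unname(cfg$integrationRho),
               c(0.7, 0.7))             # scalar expands to both groups
  expect_setequal(names(cfg$integrationRho),
                  c("subterranean", "non-subterranean"))
})

test_that("species shape simulation is deterministic and structured", {
  cfg <- generatorConfig(nSpecies = 8, seed = 11)
  s1 <- simulateSpeciesShapes(cfg)
  s2 <- simulateSpeciesShapes(cfg)
  expect_identical(s1$humerus$means, s2$humerus$means)
  expect_identical(s1$species, s2$species)
  expect_equal(dim(s1$humerus$means), c(36L, 2L, 8L))
  expect_equal(dim(s1$mandible$means), c(38L, 2L, 8L))
  expect_setequal(unique(s1$species$group),
                  c("subterranean", "non-subterranean"))
})

test_that("clade assignment keeps one group monophyletic", {
  cfg <- generatorConfig(nSpecies = 12, groupAssignment = "clade", seed = 12)
  s <- simulateSpeciesShapes(cfg)
  sub <- s$species$species[s$species$group == "subterranean"]
  expect_true(ape::is.monophyletic(s$tree, sub))
})

test_that("the realized disparity ratio matches the configuration", {
  for (ratio in c(2, 4)) {
    cfg <- generatorConfig(nSpecies = 20, disparityRatio = ratio, seed = 13)
    s <- simulateSpeciesShapes(cfg)
    g <- s$species$group
    for (str in c("humerus", "mandible")) {
      Y <- t(apply(s[[str]]$means, 3, c))
      v <- vapply(c("subterranean", "non-subterranean"), function(l) {
        R <- scale(Y[g == l, , drop = FALSE], scale = FALSE)
        sum(R^2) / sum(g == l)
      }, numeric(1))
      expect_lt(abs(v[2] / v[1] - ratio) / ratio, 0.1)
    }
  }
})

test_that("cross-structure integration increases with rho", {
  rpls <- vapply(c(0.1, 0.95), function(rho) {
    cfg <- generatorConfig(nSpecies = 60, integrationRho = rho,
                           groupMeanOffset = 0, groupAssignment = "random",
                           seed = 14)
    s <- simulateSpeciesShapes(cfg)
    twoBlockPls(t(apply(s$humerus$means, 3, c)),
                t(apply(s$mandible$means, 3, c)), nperm = 0)@cors[1]
  }, numeric(1))
  expect_gt(rpls[2], rpls[1])
})

test_that("rho = 1 makes the shared factor identical across structures", {
  cfg <- generatorConfig(nSpecies = 10, integrationRho = 1, seed = 15)
  s <- simulateSpeciesShapes(cfg)
  expect_equal(s$humerus$latent, s$mandible$latent, tolerance = 1e-12)
  b <- simulateCorrelatedBlocks(50, 4, 4, rho = 1, seed = 16)
  expect_equal(abs(cor(b$Y1[, 1], b$Y2[, 1])), 1, tolerance = 1e-12)
})

test_that("noise-free specimens reproduce their species means", {
  cfg <- generatorConfig(nSpecies = 5, sampleSizes = "balanced",
                         nPerSpecies = 3, specimenNoiseSd = 0,
                         allometrySlope = 0, seed = 17)
  s <- simulateSpeciesShapes(cfg)
  sp <- simulateSpecimens(s$humerus$means, cfg, s$species)
  a <- coords(sp$landmarks)
  for (i in seq_len(dim(a)[3])) {
    shp <- a[, , i] / sp$table$cs[i]
    expect_equal(unname(shp),
                 unname(s$humerus$means[, , sp$table$species[i]]),
                 tolerance = 1e-12)
  }
})

test_that("specimen tables and replicates follow the configuration", {
  cfg <- generatorConfig(nSpecies = 6, seed = 18)   # table1-style sizes
  s <- simulateSpeciesShapes(cfg)
  sp <- simulateSpecimens(s$humerus$means, cfg, s$species)
  ni <- table(sp$table$species)
  expect_true(all(ni >= 2 & ni <= 59))
  expect_null(sp$replicates)
  expect_silent(validateSpecimenTable(sp$table))
  cfgR <- generatorConfig(nSpecies = 4, sampleSizes = "balanced",
                          nPerSpecies = 2, replicateNoiseSd = 1e-3, seed = 19)
  sR <- simulateSpeciesShapes(cfgR)
  spR <- simulateSpecimens(sR$humerus$means, cfgR, sR$species)
  expect_length(spR$replicates, 3L)
  for (r in spR$replicates) expect_s4_class(r, "LandmarkSet")
})

test_that("warp samples center on the template", {
  w <- simulateWarpSample(200, exponent = 1, seed = 20)
  tpl <- makeTemplate("humerus36")$template
  expect_equal(apply(w$shapes, c(1, 2), mean), tpl, tolerance = 0.01)
  expect_identical(dim(w$shapes), c(36L, 2L, 200L))
})
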