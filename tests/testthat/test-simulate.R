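test_that("the study generator is reproducible and carries its truth", {
  cls <- classSubset(c("CE", "PC"), c_max = 32)
  p <- simulationParams(n_control_lines = 2, n_ald_lines = 2,
                        replicates = 2, timepoints = c(50, 100))
  a <- simulateStudy(p, cls, seed = 99)
  b <- simulateStudy(p, cls, seed = 99)
  expect_identical(abundances(a$experiment), abundances(b$experiment))
  expect_identical(a$truth$line_intercepts, b$truth$line_intercepts)
  c_ <- simulateStudy(p, cls, seed = 100)
  expect_false(identical(abundances(a$experiment),
                         abundances(c_$experiment)))
  # design shape
  d <- designTable(a$experiment)
  expect_equal(nrow(d), 4 * 2 * 2)
  expect_equal(sort(unique(d$timepoint)), c(50, 100))
})

test_that("the noiseless null study is constant across lines and genotypes", {
  p <- simulationParams(n_control_lines = 2, n_ald_lines = 3,
                        replicates = 2, sigma_line = 0, sigma_e = 0,
                        vlcfa_effect = 0)
  sim <- simulateStudy(p, classSubset("PC", c_max = 30), seed = 7)
  au <- abundances(sim$experiment)
  d <- designTable(sim$experiment)
  for (tp in unique(d$timepoint)) {
    cols <- which(d$timepoint == tp)
    expect_true(all(apply(au[, cols, drop = FALSE], 1,
                          function(v) diff(range(v)) == 0)))
  }
})

test_that("the VLCFA hinge effect is encoded in the truth and realized empirically", {
  cls <- classSubset("CE", c_min = 36, c_max = 36)  # C0 + 10 for 1 chain
  cls$db_max <- 0
  p <- simulationParams(n_control_lines = 3, n_ald_lines = 3,
                        replicates = 3, timepoints = 50,
                        vlcfa_effect = 0.1)
  sim <- simulateStudy(p, cls, seed = 1)
  expect_equal(sim$truth$species$effect_log2, 1.0)
  # empirical log2 FC over independent replications matches the truth
  fcs <- sapply(1:60, function(i) {
    s <- simulateStudy(p, cls, seed = 5000 + i)
    au <- abundances(s$experiment)
    d <- designTable(s$experiment)
    log2(mean(au[1, d$genotype == "ALD"]) /
           mean(au[1, d$genotype == "CTRL"]))
  })
  # MC error of the mean is ~0.03 here
  expect_lt(abs(mean(fcs) - 1.0), 0.1)
})

test_that("simulated spectra round-trip through annotation at zero mass error", {
  cls <- classSubset(c("CE", "PC", "TG"), c_max = 50)
  mix <- shippedMix()
  db <- buildDatabase(cls, shippedAdducts(), mix)
  sim <- simulateStudy(simulationParams(n_control_lines = 2,
                                        n_ald_lines = 2, replicates = 1,
                                        timepoints = 50), cls, seed = 2)
  spec <- simulateFeatureSpectra(db, sim$experiment, cls, mix,
                                 ppm_sigma = 0, decoy_rate = 0, seed = 2)
  ann <- matchFeatures(spec$features, db, tol_ppm = 5)$annotations
  truth <- spec$truth
  m <- merge(ann, truth, by = "feature_id", suffixes = c("", ".t"))
  expect_equal(nrow(m), nrow(truth))  # every feature annotated
  expect_true(all(m$species == m$species.t & m$adduct == m$adduct.t))
})

test_that("decoy features avoid all candidates by three tolerances", {
  cls <- classSubset(c("CE", "PC"), c_max = 36)
  mix <- shippedMix()
  db <- buildDatabase(cls, shippedAdducts(), mix)
  sim <- simulateStudy(simulationParams(n_control_lines = 2,
                                        n_ald_lines = 2, replicates = 1,
                                        timepoints = 50), cls, seed = 3)
  spec <- simulateFeatureSpectra(db, sim$experiment, cls, mix,
                                 ppm_sigma = 2, decoy_rate = 0.2,
                                 tol_ppm = 5, seed = 3)
  truth <- spec$truth
  expect_equal(sum(truth$decoy),
               round(0.2 / 0.8 * sum(!truth$decoy)))
  info <- featureInfo(spec$features)
  e <- dbEntries(db)
  for (i in which(truth$decoy)) {
    same <- e$polarity == info$polarity[i]
    expect_gt(min(abs(ppmError(info$mz[i], e$mz[same]))), 15)
  }
  # decoys are never annotated at the default tolerance
  ann <- matchFeatures(spec$features, db, tol_ppm = 5)$annotations
  expect_equal(sum(ann$feature_id %in% truth$feature_id[truth$decoy]), 0L)
})

test_that("spectra -> annotation -> quantification reproduces the study at zero noise", {
  cls <- classSubset(c("CE", "PC"), c_max = 36)
  mix <- shippedMix()
  db <- buildDatabase(cls, shippedAdducts(), mix)
  sim <- simulateStudy(simulationParams(n_control_lines = 2,
                                        n_ald_lines = 2, replicates = 2,
                                        timepoints = c(50, 100)),
                       cls, seed = 4)
  spec <- simulateFeatureSpectra(db, sim$experiment, cls, mix,
                                 ppm_sigma = 0, decoy_rate = 0, seed = 4)
  ann <- matchFeatures(spec$features, db, tol_ppm = 5)
  se <- quantifyTable(ann$annotations, spec$features,
                      designTable(sim$experiment), mix, cls)
  truthAu <- abundances(sim$experiment)
  shared <- intersect(rownames(abundances(se)), rownames(truthAu))
  expect_gt(cor(as.vector(log(abundances(se)[shared, ])),
                as.vector(log(truthAu[shared, ]))), 0.99)
})
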