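test_that("internal-standard normalization follows the semi-quant rule", {
  expect_equal(normalizeToStandard(100000, 100000, 2.0), 2.0)
  expect_equal(normalizeToStandard(0, 50000, 0.5), 0.0)
  expect_equal(normalizeToStandard(75000, 50000, 0.1), 0.15)
  expect_error(normalizeToStandard(1, 0, 1), "> 0")
  expect_error(normalizeToStandard(1, 1, 0), "> 0")
  expect_error(normalizeToStandard(-1, 1, 1), ">= 0")
})

# shared simulated fixture: small CE+PC study, noiseless spectra
quantFixture <- function(ppm_sigma = 0, drift = NULL, seed = 42) {
  cls <- classSubset(c("CE", "PC"), c_max = 36)
  mix <- shippedMix()
  db <- buildDatabase(cls, shippedAdducts(), mix)
  params <- simulationParams(n_control_lines = 2, n_ald_lines = 2,
                             replicates = 2, timepoints = c(50, 100))
  sim <- simulateStudy(params, cls, seed = seed)
  spec <- simulateFeatureSpectra(db, sim$experiment, cls, mix,
                                 ppm_sigma = ppm_sigma, decoy_rate = 0,
                                 drift = drift, seed = seed)
  ann <- matchFeatures(spec$features, db, tol_ppm = 5)
  list(cls = cls, mix = mix, db = db, sim = sim, spec = spec, ann = ann)
}

test_that("quantification recovers generator abundances exactly at zero noise", {
  fx <- quantFixture()
  se <- quantifyTable(fx$ann$annotations, fx$spec$features,
                      designTable(fx$sim$experiment), fx$mix, fx$cls)
  truthAu <- abundances(fx$sim$experiment)
  shared <- intersect(rownames(abundances(se)), rownames(truthAu))
  expect_gt(length(shared), 100)
  expect_equal(abundances(se)[shared, ], truthAu[shared, ],
               tolerance = 1e-12)
})

test_that("quantification is invariant to per-sample detector drift and scales linearly", {
  fx <- quantFixture()
  n <- ncol(abundances(fx$sim$experiment))
  set.seed(1)
  fx2 <- quantFixture(drift = exp(rnorm(n, 0, 0.5)))
  se1 <- quantifyTable(fx$ann$annotations, fx$spec$features,
                       designTable(fx$sim$experiment), fx$mix, fx$cls)
  se2 <- quantifyTable(fx2$ann$annotations, fx2$spec$features,
                       designTable(fx2$sim$experiment), fx2$mix, fx2$cls)
  expect_equal(abundances(se1), abundances(se2), tolerance = 1e-12)
  # doubling every analyte area doubles the values
  info <- featureInfo(fx$spec$features)
  areas <- featureAreas(fx$spec$features)
  isFeat <- fx$ann$annotations$feature_id[fx$ann$annotations$is_standard]
  scale2 <- ifelse(rownames(areas) %in% isFeat, 1, 2)
  ft2 <- FeatureTable(info, areas * scale2)
  se3 <- quantifyTable(fx$ann$annotations, ft2,
                       designTable(fx$sim$experiment), fx$mix, fx$cls)
  expect_equal(abundances(se3), 2 * abundances(se1), tolerance = 1e-12)
})

test_that("classes lacking an internal-standard feature are dropped with a warning", {
  fx <- quantFixture()
  ann <- fx$ann$annotations
  # remove the CE standard's annotation
  ann <- ann[!(ann$species == "CE(16:0)-d7"), ]
  expect_warning(
    se <- quantifyTable(ann, fx$spec$features,
                        designTable(fx$sim$experiment), fx$mix, fx$cls),
    "CE"
  )
  expect_false("CE" %in% speciesData(se)$class_code)
  expect_true("PC" %in% speciesData(se)$class_code)
})

test_that("line medians use the median (mean of central pair when even)", {
  design <- makeDesign(n_ctrl = 1, n_ald = 1, reps = 3, tps = 50)
  au <- matrix(c(1, 2, 30, 4, 5, 6,
                 7, 8, 9, 10, 11, 12), nrow = 2, byrow = TRUE,
               dimnames = list(c("PC(34:1)", "PC(36:2)"), design$sample_id))
  se <- makeExperiment(au, "PC", c(34, 36), c(1, 2), 2, design)
  med <- medianByLine(se)
  ctrlCol <- designTable(med)$line_id == "CTRL01"
  expect_equal(unname(abundances(med)["PC(34:1)", ctrlCol]), 2)
  # single replicate: identity
  one <- se[, designTable(se)$replicate == 1]
  med1 <- medianByLine(one)
  for (ln in c("CTRL01", "ALD01")) {
    expect_equal(
      unname(abundances(med1)[, designTable(med1)$line_id == ln]),
      unname(abundances(one)[, designTable(one)$line_id == ln]))
  }
  # even replicate count: mean of the central pair
  two <- se[, designTable(se)$replicate %in% 1:2]
  expect_equal(unname(abundances(medianByLine(two))["PC(34:1)",
                                                    ctrlCol]), 1.5)
})

test_that("median aggregation commutes with replicate relabeling", {
  params <- simulationParams(n_control_lines = 2, n_ald_lines = 2,
                             replicates = 3, timepoints = c(50, 100))
  sim <- simulateStudy(params, classSubset("PC", c_max = 30), seed = 3)
  se <- sim$experiment
  d <- designTable(se)
  set.seed(8)
  perm <- unlist(lapply(split(seq_len(nrow(d)),
                              paste(d$line_id, d$timepoint)), sample),
                 use.names = FALSE)
  d2 <- d[perm, ]
  d2$replicate <- d$replicate  # relabel replicates after shuffling
  se2 <- LipidomicsExperiment(abundances(se)[, perm], speciesData(se), d2)
  expect_equal(abundances(medianByLine(se)), abundances(medianByLine(se2)))
})
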