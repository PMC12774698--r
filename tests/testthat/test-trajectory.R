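test_that("class Z-scores standardize across cells and flag constants", {
  design <- makeDesign(n_ctrl = 3, n_ald = 0, reps = 1, tps = 50)
  design <- design[design$genotype == "CTRL", ]
  au <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE,
               dimnames = list(c("PC(34:1)", "TG(52:2)"), design$sample_id))
  se <- makeExperiment(au, c("PC", "TG"), c(34, 52), c(1, 2), c(2, 3),
                       design)
  cz <- classZScores(se)
  expect_equal(unname(cz$z["PC", ]), c(-1, 0, 1))
  expect_equal(unname(cz$z["TG", ]), c(0, 0, 0))
  expect_equal(cz$flagged, "TG")
  # permutation equivariance
  perm <- c(3, 1, 2)
  se2 <- makeExperiment(au[, perm], c("PC", "TG"), c(34, 52), c(1, 2),
                        c(2, 3), design[perm, ])
  expect_equal(classZScores(se2)$z[, designTable(se)$sample_id[perm]],
               cz$z[, perm])
})

test_that("Z-scores are invariant to per-class affine rescaling", {
  sim <- simulateStudy(simulationParams(n_control_lines = 2,
                                        n_ald_lines = 2, replicates = 1),
                       classSubset(c("PC", "CE"), c_max = 30), seed = 5)
  se <- sim$experiment
  cz1 <- classZScores(se)
  se2 <- LipidomicsExperiment(abundances(se) * 7.3, speciesData(se),
                              designTable(se))
  expect_equal(classZScores(se2)$z, cz1$z, tolerance = 1e-12)
})

test_that("LOESS reproduces polynomials and matches the reference implementation", {
  xx <- seq(0, 10, length.out = 25)
  # exact polynomial reproduction at degree >= polynomial order
  yl <- 1 + 2 * xx
  expect_lt(max(abs(loessSmooth(xx, yl, 0.5, 1)$fitted - yl)), 1e-8)
  yq <- 2 + 3 * xx - 0.5 * xx^2
  expect_lt(max(abs(loessSmooth(xx, yq, 0.5, 2)$fitted - yq)), 1e-8)
  expect_equal(loessSmooth(xx, rep(4, 25), 0.75, 2)$fitted, rep(4, 25))
  # noisy sine vs stats::loess (direct surface), several spans/degrees
  set.seed(42)
  x <- sort(runif(60, 0, 2 * pi))
  y <- sin(x) + rnorm(60, 0, 0.2)
  for (sp in c(0.3, 0.75)) {
    for (dg in 1:2) {
      ref <- predict(stats::loess(y ~ x, span = sp, degree = dg,
                                  surface = "direct",
                                  family = "gaussian"),
                     newdata = data.frame(x = sort(unique(x))))
      expect_lt(max(abs(loessSmooth(x, y, sp, dg)$fitted - ref)), 1e-6)
    }
  }
  # span -> 1, degree 1 equals global least squares on linear data
  ylin <- unname(stats::fitted(stats::lm(y ~ x)))
  expect_lt(max(abs(loessSmooth(x, ylin, 1, 1)$fitted - ylin)), 1e-6)
  expect_error(loessSmooth(1:3, 1:3, 0.5, 2), "distinct x")
})

test_that("fold-change curves: identity contrast is flat zero, ratios are exact", {
  design <- makeDesign(n_ctrl = 3, n_ald = 0, reps = 1, tps = c(50, 100))
  design <- design[design$genotype == "CTRL", ]
  sp <- paste0("PC(", 30:39, ":1)")
  set.seed(2)
  base <- matrix(rlnorm(10 * 6), 10, 6, dimnames = list(sp, design$sample_id))
  is100 <- design$timepoint == 100
  base[, is100] <- base[, !is100]  # day 100 identical to day 50
  se <- makeExperiment(base, "PC", 30:39, 1, 2, design)
  fc <- fcByChainProperty(se, "c_total", c("timepoint", "50", "100"),
                          line_median = FALSE)
  expect_equal(fc$curves$mean_log2fc, rep(0, nrow(fc$curves)))
  expect_equal(fc$curves$loess_fc, rep(0, nrow(fc$curves)),
               tolerance = 1e-10)
  # 4x comparison mean -> log2 FC = 2
  base[, is100] <- 4 * base[, !is100]
  se <- makeExperiment(base, "PC", 30:39, 1, 2, design)
  fc <- fcByChainProperty(se, "c_total", c("timepoint", "50", "100"),
                          line_median = FALSE)
  expect_equal(fc$curves$mean_log2fc, rep(2, nrow(fc$curves)))
})

test_that("fold-change curves negate when the contrast groups swap", {
  sim <- simulateStudy(simulationParams(n_control_lines = 3,
                                        n_ald_lines = 3, replicates = 2,
                                        timepoints = c(50, 100)),
                       classSubset(c("CE", "PC"), c_max = 40), seed = 11)
  a <- fcByChainProperty(sim$experiment, "c_total",
                         c("genotype", "CTRL", "ALD"))
  b <- fcByChainProperty(sim$experiment, "c_total",
                         c("genotype", "ALD", "CTRL"))
  expect_equal(a$curves$mean_log2fc, -b$curves$mean_log2fc,
               tolerance = 1e-12)
  expect_equal(a$species$log2fc, -b$species$log2fc, tolerance = 1e-12)
})

test_that("PCA separates the dominant axis and is rotation invariant", {
  design <- makeDesign(n_ctrl = 1, n_ald = 1, reps = 1, tps = 50)
  au <- matrix(c(1, 8, 3, 3), nrow = 2, byrow = TRUE,
               dimnames = list(c("PC(34:1)", "PC(36:2)"),
                               design$sample_id))
  se <- makeExperiment(au, "PC", c(34, 36), c(1, 2), 2, design)
  p <- pcaScores(se, log = FALSE)
  expect_equal(p$explained[1], 1)
  expect_true(all(diff(p$explained) <= 1e-12))
  # orthogonal rotation of the centered matrix leaves the spectrum unchanged
  set.seed(13)
  xc <- scale(matrix(rnorm(60), 6, 10), scale = FALSE)  # samples x species
  q <- qr.Q(qr(matrix(rnorm(100), 10, 10)))
  s1 <- stats::prcomp(xc, center = FALSE)$sdev
  s2 <- stats::prcomp(xc %*% q, center = FALSE)$sdev
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("PC1 orders samples by timepoint when the trajectory dominates", {
  params <- simulationParams(n_control_lines = 3, n_ald_lines = 1,
                             replicates = 3, sigma_line = 0.05,
                             sigma_e = 0.1, vlcfa_effect = 0)
  rhos <- sapply(1:5, function(s) {
    sim <- simulateStudy(params, classSubset(c("PC", "SM[d]", "GM3[d]"),
                                             c_max = 40), seed = 100 + s)
    p <- pcaScores(sim$experiment)
    abs(cor(p$scores[, 1], designTable(sim$experiment)$timepoint,
            method = "spearman"))
  })
  expect_true(all(rhos > 0.9))
})
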