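test_that("database entry counts equal the species x adduct product", {
  d <- makeClassDef(c_min = 30L, c_max = 32L, db_min = 0L, db_max = 2L)
  db <- buildDatabase(d, shippedAdducts(), constraint = NULL)
  expect_equal(nrow(dbEntries(db)), 9L * 3L)  # 2 pos + 1 neg adducts
  # empty class list gives an empty database
  empty <- d[integer(0), ]
  expect_equal(nrow(dbEntries(buildDatabase(empty, shippedAdducts()))), 0L)
  # duplicate class codes rejected
  expect_error(buildDatabase(rbind(d, d), shippedAdducts()), "duplicate")
})

test_that("shipped database size equals an independent recount", {
  cls <- shippedClasses()
  db <- buildDatabase(cls, shippedAdducts(), shippedMix())
  # brute-force recount: nested loops over classes, C, db, adducts
  n <- 0L
  for (i in seq_len(nrow(cls))) {
    nAdd <- length(cls$adducts_pos[[i]]) + length(cls$adducts_neg[[i]])
    for (C in cls$c_min[i]:cls$c_max[i]) {
      for (db_ in cls$db_min[i]:cls$db_max[i]) {
        if (db_ <= floor(C / 2)) n <- n + nAdd
      }
    }
  }
  # plus standards not present as grid species: the deuterated CE, and
  # PI(16:0) whose carbon total lies below the PI enumeration range
  for (code in c("CE", "PI")) {
    cl <- cls[cls$class_code == code, ]
    n <- n + length(cl$adducts_pos[[1]]) + length(cl$adducts_neg[[1]])
  }
  expect_equal(nrow(dbEntries(db)), n)
  e <- dbEntries(db)
  expect_false(anyDuplicated(paste(e$species, e$adduct)) > 0)
})

test_that("ppm error is the relative deviation in parts per million", {
  expect_equal(ppmError(500.0, 500.0), 0)
  expect_equal(ppmError(500.0025, 500.0), 5.0)
  # direct formula: 2e-6 / (1 - 2e-6) * 1e6, i.e. +2.0 ppm
  expect_equal(ppmError(676.4923, 676.4923 * (1 - 2e-6)),
               2e-6 / (1 - 2e-6) * 1e6, tolerance = 1e-9)
  expect_equal(ppmError(676.4923, 676.4923 * (1 - 2e-6)), 2.0,
               tolerance = 1e-5)
  expect_error(ppmError(500, 0), "> 0")
})

test_that("indexed range queries equal a linear scan", {
  db <- buildDatabase(classSubset(c("CE", "PC", "TG")), shippedAdducts())
  e <- dbEntries(db)
  set.seed(21)
  for (i in 1:200) {
    mz <- runif(1, 350, 1300)
    pol <- sample(c("+", "-"), 1)
    tol <- runif(1, 1, 50)
    got <- mzQuery(db, mz, pol, tol)
    want <- e[e$polarity == pol & abs(ppmError(mz, e$mz)) <= tol, ]
    expect_equal(got$species, want$species)
    expect_equal(got$adduct, want$adduct)
  }
})

test_that("feature matching picks the nearest candidate within tolerance", {
  db <- buildDatabase(classSubset("PC"), shippedAdducts())
  e <- dbEntries(db)
  hit <- e[e$species == "PC(34:1)" & e$adduct == "[M+H]+", ]
  info <- data.frame(
    feature_id = c("A", "B"),
    mz = c(hit$mz, hit$mz * (1 + 10e-6)),
    polarity = "+", rt = NA_real_, stringsAsFactors = FALSE
  )
  ft <- FeatureTable(info, matrix(1, 2, 1, dimnames = list(NULL, "s1")))
  m <- matchFeatures(ft, db, tol_ppm = 5)
  expect_equal(nrow(m$annotations), 1L)
  expect_equal(m$annotations$species, "PC(34:1)")
  expect_equal(m$annotations$adduct, "[M+H]+")
  expect_equal(m$annotations$ppm_error, 0)
  expect_gte(m$annotations$ambiguity_count, 1L)
  expect_equal(m$unmatched, "B")
})

test_that("matched feature set grows monotonically with tolerance", {
  db <- buildDatabase(classSubset(c("PC", "PE")), shippedAdducts())
  e <- dbEntries(db)
  set.seed(5)
  pick <- e[sample(nrow(e), 40), ]
  info <- data.frame(feature_id = sprintf("F%02d", 1:40),
                     mz = pick$mz * (1 + rnorm(40, 0, 4e-6)),
                     polarity = pick$polarity, rt = NA_real_,
                     stringsAsFactors = FALSE)
  ft <- FeatureTable(info, matrix(1, 40, 1, dimnames = list(NULL, "s1")))
  prev <- character(0)
  for (tol in c(1, 2, 5, 10, 20)) {
    got <- matchFeatures(ft, db, tol_ppm = tol)$annotations$feature_id
    expect_true(all(prev %in% got))
    prev <- got
  }
})

test_that("zero-error features whose neighbours are far recover exactly", {
  db <- buildDatabase(classSubset(c("CE", "PC", "TG")), shippedAdducts(),
                      shippedMix())
  e <- dbEntries(db)
  # nearest-neighbour distance in ppm within polarity
  nnppm <- sapply(seq_len(nrow(e)), function(i) {
    same <- e$polarity == e$polarity[i]
    d <- abs(e$mz[same] - e$mz[i]) / e$mz[i] * 1e6
    min(d[d > 0])
  })
  iso <- which(nnppm > 5)
  set.seed(9)
  iso <- iso[sample(length(iso), 150)]
  info <- data.frame(feature_id = sprintf("F%03d", seq_along(iso)),
                     mz = e$mz[iso], polarity = e$polarity[iso],
                     rt = NA_real_, stringsAsFactors = FALSE)
  ft <- FeatureTable(info, matrix(1, length(iso), 1,
                                  dimnames = list(NULL, "s1")))
  ann <- matchFeatures(ft, db, tol_ppm = 5)$annotations
  expect_equal(nrow(ann), length(iso))
  expect_equal(ann$species, e$species[iso])
  expect_equal(ann$adduct, e$adduct[iso])
})

test_that("retention-time windows gate candidate classes", {
  db <- buildDatabase(classSubset("PC"), shippedAdducts())
  hit <- dbEntries(db)[1, ]
  info <- data.frame(feature_id = "A", mz = hit$mz, polarity = hit$polarity,
                     rt = 12, stringsAsFactors = FALSE)
  ft <- FeatureTable(info, matrix(1, 1, 1, dimnames = list(NULL, "s1")))
  win <- data.frame(class_code = "PC", rt_min = 1, rt_max = 5)
  m <- matchFeatures(ft, db, tol_ppm = 5, rt_windows = win)
  expect_equal(m$unmatched, "A")
  win$rt_max <- 14
  m <- matchFeatures(ft, db, tol_ppm = 5, rt_windows = win)
  expect_equal(nrow(m$annotations), 1L)
  expect_true(m$annotations$rt_pass)
})
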