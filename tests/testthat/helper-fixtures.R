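# Shared fixtures: all built in code at test time.

shippedClasses <- function() readClassDefinitions()
shippedAdducts <- function() readAdductTable()
shippedMix <- function() readStandardsMix()

# subset of the shipped class set (by code), optionally with narrowed ranges
classSubset <- function(codes, c_min = NULL, c_max = NULL) {
  cls <- shippedClasses()
  cls <- cls[cls$class_code %in% codes, , drop = FALSE]
  if (!is.null(c_min)) cls$c_min <- pmax(cls$c_min, c_min)
  if (!is.null(c_max)) cls$c_max <- pmin(cls$c_max, c_max)
  cls
}

# a one-off single-row class definition in the in-memory format
makeClassDef <- function(class_code = "XX", base_formula = "C8H16NO8P",
                         n_chains = 2L, c_min = 30L, c_max = 32L,
                         db_min = 0L, db_max = 2L,
                         adducts_pos = c("[M+H]+", "[M+Na]+"),
                         adducts_neg = "[M-H]-",
                         internal_standard = "PC(28:0)") {
  df <- data.frame(class_code = class_code, base_formula = base_formula,
                   n_chains = n_chains, c_min = c_min, c_max = c_max,
                   db_min = db_min, db_max = db_max,
                   internal_standard = internal_standard,
                   stringsAsFactors = FALSE)
  df$adducts_pos <- list(adducts_pos)
  df$adducts_neg <- list(adducts_neg)
  df
}

# small abundance table built directly (no simulation)
makeExperiment <- function(au, class_code, c_total, db_total, n_chains,
                           design) {
  rd <- data.frame(species = rownames(au), class_code = class_code,
                   c_total = c_total, db_total = db_total,
                   n_chains = n_chains, stringsAsFactors = FALSE)
  LipidomicsExperiment(au, rd, design)
}

# minimal design fixture: nLines per genotype (0 allowed), reps, timepoints
makeDesign <- function(n_ctrl = 2, n_ald = 2, reps = 2, tps = c(50, 100),
                       region = "hCO") {
  lines <- c(if (n_ctrl) sprintf("CTRL%02d", seq_len(n_ctrl)),
             if (n_ald) sprintf("ALD%02d", seq_len(n_ald)))
  genotype <- rep(c("CTRL", "ALD"), c(n_ctrl, n_ald))
  grid <- expand.grid(replicate = seq_len(reps), timepoint = tps,
                      line = seq_along(lines), KEEP.OUT.ATTRS = FALSE)
  data.frame(
    sample_id = sprintf("%s_%s_d%03d_r%d", lines[grid$line], region,
                        grid$timepoint, grid$replicate),
    line_id = lines[grid$line], genotype = genotype[grid$line],
    region = region, timepoint = grid$timepoint,
    replicate = grid$replicate, stringsAsFactors = FALSE
  )
}

# small end-to-end input set written to a temp dir
makePipelineInputs <- function(dir, seed = 12) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cls <- classSubset(c("CE", "PC", "TG"), c_max = 40)
  # serialize the narrowed class set so the pipeline reads it from file
  flat <- cls
  flat$adducts_pos <- vapply(cls$adducts_pos, paste, "", collapse = ",")
  flat$adducts_neg <- vapply(cls$adducts_neg, paste, "", collapse = ",")
  classFile <- file.path(dir, "classes.tsv")
  utils::write.table(flat, classFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mix <- shippedMix()
  db <- buildDatabase(cls, shippedAdducts(), mix)
  sim <- simulateStudy(simulationParams(n_control_lines = 2,
                                        n_ald_lines = 2, replicates = 2,
                                        timepoints = c(50, 100)),
                       cls, seed = seed)
  spec <- simulateFeatureSpectra(db, sim$experiment, cls, mix,
                                 ppm_sigma = 2, decoy_rate = 0.1,
                                 seed = seed)
  featureFile <- file.path(dir, "features.tsv")
  writeFeatureTable(spec$features, featureFile)
  designFile <- file.path(dir, "design.csv")
  writeStudyDesign(designTable(sim$experiment), designFile)
  list(class_file = classFile, feature_file = featureFile,
       design_file = designFile, sim = sim)
}

# random valid formula as named integer vector (for property tests)
randomFormula <- function() {
  els <- names(isotopeMasses())
  k <- sample(2:6, 1)
  pick <- sample(els, k)
  f <- sample(1:80, k, replace = TRUE)
  names(f) <- pick
  f[order(match(names(f), els))]
}
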