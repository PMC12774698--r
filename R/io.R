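## Tabular readers/writers (TSV dialect: UTF-8, tab-separated, '.' decimal),
## pipeline configuration and the end-to-end runner.

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
}

#' Read a picked LC-MS feature table
#'
#' TSV with header \code{feature_id}, \code{mz}, \code{polarity},
#' \code{rt}, then one peak-area column per sample.
#'
#' @param path File path.
#' @return A \linkS4class{FeatureTable}.
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("feature_id", "mz", "polarity", "rt")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$feature_id)) {
    stop("duplicate feature_id: ",
         paste(unique(df$feature_id[duplicated(df$feature_id)]),
               collapse = ", "))
  }
  if (!is.numeric(df$mz)) stop("non-numeric m/z column")
  sampleCols <- setdiff(names(df), need)
  if (!length(sampleCols)) stop("feature table has no sample columns")
  areas <- as.matrix(df[, sampleCols, drop = FALSE])
  if (!is.numeric(areas)) stop("non-numeric peak-area column")
  FeatureTable(df[, need], areas)
}

#' Write a feature table
#'
#' Inverse of \code{\link{readFeatureTable}} (lossless round trip).
#'
#' @param features A \linkS4class{FeatureTable}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  df <- cbind(featureInfo(features),
              as.data.frame(featureAreas(features), check.names = FALSE))
  .writeTsv(df, path)
  invisible(path)
}

#' Read a study-design table
#'
#' CSV with columns \code{sample_id}, \code{line_id}, \code{genotype}
#' (CTRL/ALD), \code{region} (hCO/hSO), \code{timepoint} (integer days),
#' \code{replicate}.
#'
#' @param path File path.
#' @return data.frame, one row per sample.
#' @export
readStudyDesign <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "line_id", "genotype", "region", "timepoint",
            "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("study design lacks column(s): ", paste(missing, collapse = ", "))
  }
  key <- paste(df$line_id, df$region, df$timepoint, df$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (line, region, timepoint, replicate) in design")
  }
  if (!all(df$genotype %in% c("CTRL", "ALD"))) {
    stop("genotype must be 'CTRL' or 'ALD'")
  }
  byLine <- split(df$genotype, df$line_id)
  if (any(vapply(byLine, function(g) length(unique(g)), 1L) > 1L)) {
    stop("genotype must be constant within a line")
  }
  df
}

#' Write a study-design table (CSV)
#'
#' @param design data.frame as from \code{\link{readStudyDesign}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeStudyDesign <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an abundance table with its design metadata
#'
#' TSV with a \code{#}-prefixed metadata header block (one line per design
#' field, aligned with the sample columns), then species rows with their
#' class metadata.
#'
#' @param x A \linkS4class{LipidomicsExperiment}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeAbundanceTable <- function(x, path) {
  d <- designTable(x)
  meta <- speciesData(x)
  metaCols <- c("species", "class_code", "c_total", "db_total", "n_chains")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (field in c("line_id", "genotype", "region", "timepoint",
                  "replicate")) {
    writeLines(paste(c(paste0("#", field), rep("", length(metaCols) - 1L),
                       as.character(d[[field]])), collapse = "\t"), con)
  }
  header <- paste(c(metaCols, d$sample_id), collapse = "\t")
  writeLines(header, con)
  au <- abundances(x)
  body <- cbind(meta[, metaCols, drop = FALSE],
                as.data.frame(au, check.names = FALSE))
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an abundance table written by \code{\link{writeAbundanceTable}}
#'
#' @param path File path.
#' @return A \linkS4class{LipidomicsExperiment}.
#' @export
readAbundanceTable <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  metaLines <- grep("^#", lines)
  meta <- list()
  for (i in metaLines) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    meta[[sub("^#", "", parts[1L])]] <- parts[-(1:5)]
  }
  body <- utils::read.delim(text = lines[-metaLines],
                            stringsAsFactors = FALSE, check.names = FALSE)
  metaCols <- c("species", "class_code", "c_total", "db_total", "n_chains")
  au <- as.matrix(body[, setdiff(names(body), metaCols), drop = FALSE])
  design <- data.frame(
    sample_id = colnames(au), line_id = meta$line_id,
    genotype = meta$genotype, region = meta$region,
    timepoint = as.numeric(meta$timepoint),
    replicate = suppressWarnings(as.integer(meta$replicate)),
    stringsAsFactors = FALSE
  )
  LipidomicsExperiment(au, body[, metaCols], design)
}

## ---------------------------------------------------------------------------
## Pipeline configuration and runner
## ---------------------------------------------------------------------------

.CONFIG_DEFAULTS <- list(
  class_file = NULL, adduct_file = NULL, standards_file = NULL,
  feature_file = NULL, design_file = NULL, out_dir = NULL,
  tol_ppm = 5, loess_span = 0.75, loess_degree = 2,
  lmm_mode = "per_timepoint", lmm_method = "satterthwaite",
  data_level = "replicate", fdr_threshold = 0.05, seed = 1
)

#' Read and validate a pipeline configuration
#'
#' YAML file with keys \code{feature_file}, \code{design_file},
#' \code{out_dir} (required) and \code{class_file}, \code{adduct_file},
#' \code{standards_file} (default: shipped configs), \code{tol_ppm} (5),
#' \code{loess_span} (0.75), \code{loess_degree} (2), \code{lmm_mode}
#' (\code{"per_timepoint"}), \code{lmm_method} (\code{"satterthwaite"}),
#' \code{data_level} (\code{"replicate"}), \code{fdr_threshold} (0.05),
#' \code{seed} (1). Unknown keys are rejected; the validated list
#' serializes back to YAML with \code{yaml::write_yaml}.
#'
#' @param path YAML file path.
#' @return Validated named list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(.CONFIG_DEFAULTS))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  config <- utils::modifyList(.CONFIG_DEFAULTS, raw)
  validatePipelineConfig(config)
}

#' Validate a pipeline configuration list
#'
#' @param config Named list of configuration values.
#' @return The validated config (with defaults filled in).
#' @export
validatePipelineConfig <- function(config) {
  config <- utils::modifyList(.CONFIG_DEFAULTS, config)
  for (k in c("feature_file", "design_file", "out_dir")) {
    if (is.null(config[[k]])) stop("config key required: ", k)
  }
  if (is.null(config$class_file)) {
    config$class_file <- system.file("extdata", "lipid_classes.tsv",
                                     package = "lipidsum")
  }
  if (is.null(config$adduct_file)) {
    config$adduct_file <- system.file("extdata", "adducts.tsv",
                                      package = "lipidsum")
  }
  if (is.null(config$standards_file)) {
    config$standards_file <- system.file("extdata", "standards_mix.tsv",
                                         package = "lipidsum")
  }
  if (!is.numeric(config$tol_ppm) || config$tol_ppm <= 0) {
    stop("tol_ppm must be > 0")
  }
  if (config$loess_span <= 0) stop("loess_span must be > 0")
  if (!config$loess_degree %in% 0:2) stop("loess_degree must be 0, 1 or 2")
  if (!config$lmm_mode %in% c("per_timepoint", "overall")) {
    stop("lmm_mode must be 'per_timepoint' or 'overall'")
  }
  if (!config$lmm_method %in% c("satterthwaite", "wald")) {
    stop("lmm_method must be 'satterthwaite' or 'wald'")
  }
  if (!config$data_level %in% c("replicate", "line_median")) {
    stop("data_level must be 'replicate' or 'line_median'")
  }
  if (config$fdr_threshold <= 0 || config$fdr_threshold > 1) {
    stop("fdr_threshold must be in (0, 1]")
  }
  config
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp,
                       auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full annotation and analysis pipeline
#'
#' Executes build-db, annotate, normalize, trajectory and stats on the
#' configured inputs and writes all result TSVs plus a machine-readable
#' \code{manifest.json} (stage list, outputs, seed, config and its hash,
#' package version; no wall-clock state, so a rerun with the same inputs
#' and seed is bit-identical). A stage failure aborts with a stage-tagged
#' error. The stats stage needs both genotypes with at least two lines
#' each and is otherwise recorded as skipped; the fold-change-curve step
#' likewise needs at least two timepoints.
#'
#' @param config Validated configuration list
#'   (\code{\link{readPipelineConfig}} /
#'   \code{\link{validatePipelineConfig}}).
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  config <- validatePipelineConfig(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ## the manifest records the analysis parameters; the output location is
  ## excluded so reruns into different directories stay comparable
  cfgRecord <- config[setdiff(names(config), "out_dir")]
  manifest <- list(tool = "lipidsum",
                   version = as.character(utils::packageVersion("lipidsum")),
                   seed = config$seed, config = cfgRecord,
                   config_hash = .configHash(cfgRecord), stages = list())
  addStage <- function(name, status, outputs = character(0)) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(name = name, status = status, outputs = as.list(outputs))
  }
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  ## stage 1: build-db
  db <- runStage("build-db", {
    classes <- readClassDefinitions(config$class_file)
    adducts <- readAdductTable(config$adduct_file)
    mix <- readStandardsMix(config$standards_file)
    db <- buildDatabase(classes, adducts, mix)
    .writeTsv(dbEntries(db), file.path(out, "candidate_db.tsv"))
    db
  })
  classes <- readClassDefinitions(config$class_file)
  mix <- readStandardsMix(config$standards_file)
  addStage("build-db", "completed", "candidate_db.tsv")

  ## stage 2: annotate
  matched <- runStage("annotate", {
    features <- readFeatureTable(config$feature_file)
    m <- matchFeatures(features, db, tol_ppm = config$tol_ppm)
    .writeTsv(m$annotations, file.path(out, "annotations.tsv"))
    .writeTsv(data.frame(feature_id = m$unmatched),
              file.path(out, "unmatched.tsv"))
    c(m, list(features = features))
  })
  addStage("annotate", "completed", c("annotations.tsv", "unmatched.tsv"))

  ## stage 3: normalize
  se <- runStage("normalize", {
    design <- readStudyDesign(config$design_file)
    se <- quantifyTable(matched$annotations, matched$features, design, mix,
                        classes)
    writeAbundanceTable(se, file.path(out, "abundance.tsv"))
    writeAbundanceTable(medianByLine(se),
                        file.path(out, "abundance_line_median.tsv"))
    se
  })
  addStage("normalize", "completed",
           c("abundance.tsv", "abundance_line_median.tsv"))

  ## stage 4: trajectory
  trajOut <- runStage("trajectory", {
    med <- medianByLine(se)
    cz <- classZScores(med)
    tidy <- data.frame(
      class_code = rep(rownames(cz$z), ncol(cz$z)),
      sample_id = rep(colnames(cz$z), each = nrow(cz$z)),
      abundance = as.vector(cz$abundance), z = as.vector(cz$z),
      stringsAsFactors = FALSE
    )
    .writeTsv(tidy, file.path(out, "class_zscores.tsv"))
    outputs <- "class_zscores.tsv"
    tps <- sort(unique(designTable(med)$timepoint))
    if (length(tps) >= 2L) {
      curves <- list()
      for (tp in tps[-1L]) {
        for (prop in c("c_total", "db_total")) {
          fc <- fcByChainProperty(med, prop,
                                  c("timepoint", as.character(tps[1L]),
                                    as.character(tp)),
                                  span = config$loess_span,
                                  degree = config$loess_degree,
                                  line_median = FALSE)
          curves[[paste(prop, tp)]] <- cbind(property = prop, fc$curves)
        }
      }
      .writeTsv(do.call(rbind, curves), file.path(out, "fc_curves.tsv"))
      outputs <- c(outputs, "fc_curves.tsv")
    }
    pca <- pcaScores(se)
    k <- seq_len(min(5L, ncol(pca$scores)))
    .writeTsv(cbind(data.frame(sample_id = rownames(pca$scores)),
                    as.data.frame(pca$scores[, k, drop = FALSE])),
              file.path(out, "pca_scores.tsv"))
    .writeTsv(data.frame(component = seq_along(pca$explained),
                         explained = pca$explained),
              file.path(out, "pca_variance.tsv"))
    outputs <- c(outputs, "pca_scores.tsv", "pca_variance.tsv")
    outputs
  })
  addStage("trajectory", "completed", trajOut)

  ## stage 5: stats
  d <- designTable(se)
  enough <- all(vapply(c("CTRL", "ALD"), function(g) {
    length(unique(d$line_id[d$genotype == g])) >= 2L
  }, TRUE))
  if (enough) {
    statsOut <- runStage("stats", {
      res <- testDifferential(se, mode = config$lmm_mode,
                              data_level = config$data_level,
                              method = config$lmm_method)
      .writeTsv(res, file.path(out, "differential.tsv"))
      .writeTsv(volcanoTable(res), file.path(out, "volcano.tsv"))
      c("differential.tsv", "volcano.tsv")
    })
    addStage("stats", "completed", statsOut)
  } else {
    addStage("stats", "skipped (need both genotypes with >= 2 lines)")
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
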