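#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @import SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## FeatureTable: picked LC-MS features with per-sample peak areas
## ---------------------------------------------------------------------------

#' FeatureTable: picked LC-MS features
#'
#' Container for a picked LC-MS feature list: per feature an observed m/z,
#' ionization polarity, retention time, and one peak-area column per sample.
#' Peak picking itself (XCMS territory) is upstream of this package.
#'
#' @slot info data.frame with columns \code{feature_id}, \code{mz},
#'   \code{polarity} (\code{"+"} or \code{"-"}), \code{rt} (minutes,
#'   \code{NA} allowed).
#' @slot areas numeric matrix, features x samples, non-negative detector
#'   counts; rownames are feature ids.
#' @export
setClass("FeatureTable",
         representation(info = "data.frame", areas = "matrix"))

setValidity("FeatureTable", function(object) {
  info <- object@info
  msgs <- character(0)
  need <- c("feature_id", "mz", "polarity", "rt")
  if (!all(need %in% names(info))) {
    return(paste("info must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(info$feature_id)) msgs <- c(msgs, "duplicate feature_id")
  if (any(info$mz <= 0)) msgs <- c(msgs, "m/z must be > 0")
  if (!all(info$polarity %in% c("+", "-"))) {
    msgs <- c(msgs, "polarity must be '+' or '-'")
  }
  if (nrow(object@areas) != nrow(info) ||
      !identical(rownames(object@areas), info$feature_id)) {
    msgs <- c(msgs, "areas rownames must equal info$feature_id")
  }
  if (any(object@areas < 0, na.rm = TRUE)) {
    msgs <- c(msgs, "peak areas must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureTable
#'
#' @param info data.frame with \code{feature_id}, \code{mz}, \code{polarity},
#'   \code{rt}.
#' @param areas Numeric matrix features x samples (rows in \code{info} order).
#' @return A \linkS4class{FeatureTable}.
#' @export
FeatureTable <- function(info, areas) {
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  if (!"rt" %in% names(info)) info$rt <- NA_real_
  areas <- as.matrix(areas)
  rownames(areas) <- info$feature_id
  new("FeatureTable", info = info, areas = areas)
}

#' @describeIn FeatureTable Feature metadata (id, m/z, polarity, RT).
#' @param x,object A \code{FeatureTable}.
#' @export
featureInfo <- function(x) x@info

#' @describeIn FeatureTable Peak-area matrix (features x samples).
#' @export
featureAreas <- function(x) x@areas

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", nrow(object@info), "features x",
      ncol(object@areas), "samples\n")
  tab <- table(object@info$polarity)
  cat("  polarity:", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
})

## ---------------------------------------------------------------------------
## CandidateDB: theoretical (species, adduct) m/z database
## ---------------------------------------------------------------------------

#' CandidateDB: theoretical m/z database
#'
#' All (species, adduct) candidates generated from a class-definition set,
#' sorted by m/z within polarity to support range queries by parts-per-million
#' tolerance.
#'
#' @slot entries data.frame with columns \code{species}, \code{class_code},
#'   \code{c_total}, \code{db_total}, \code{n_chains}, \code{adduct},
#'   \code{polarity}, \code{mz}, \code{neutral_mass}, \code{is_standard};
#'   sorted by (polarity, mz).
#' @export
setClass("CandidateDB", representation(entries = "data.frame"))

setValidity("CandidateDB", function(object) {
  e <- object@entries
  msgs <- character(0)
  need <- c("species", "class_code", "adduct", "polarity", "mz",
            "neutral_mass", "is_standard")
  if (!all(need %in% names(e))) {
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(paste(e$species, e$adduct))) {
    msgs <- c(msgs, "duplicate (species, adduct) entry")
  }
  if (is.unsorted(order(e$polarity, e$mz)) &&
      !identical(order(e$polarity, e$mz), seq_len(nrow(e)))) {
    msgs <- c(msgs, "entries must be sorted by (polarity, mz)")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CandidateDB The sorted candidate entry table.
#' @param x,object A \code{CandidateDB}.
#' @export
dbEntries <- function(x) x@entries

setMethod("show", "CandidateDB", function(object) {
  e <- object@entries
  cat("CandidateDB:", nrow(e), "entries,",
      length(unique(e$species)), "species,",
      length(unique(e$class_code)), "classes\n")
  for (p in unique(e$polarity)) {
    sub <- e[e$polarity == p, ]
    cat("  polarity ", p, ": ", nrow(sub), " entries, m/z ",
        sprintf("%.4f-%.4f", min(sub$mz), max(sub$mz)), "\n", sep = "")
  }
})

## ---------------------------------------------------------------------------
## LipidomicsExperiment: annotated abundance table with study design
## ---------------------------------------------------------------------------

#' LipidomicsExperiment: species x sample abundances with study design
#'
#' A \linkS4class{SummarizedExperiment} holding the semi-quantitative
#' abundance matrix (assay \code{"au"}, arbitrary units) with species
#' metadata (\code{class_code}, \code{c_total}, \code{db_total},
#' \code{n_chains}) as rowData and the study design (\code{line_id},
#' \code{genotype} CTRL/ALD, \code{region} hCO/hSO, \code{timepoint} in
#' days, \code{replicate}) as colData.
#'
#' @export
setClass("LipidomicsExperiment", contains = "SummarizedExperiment")

setValidity("LipidomicsExperiment", function(object) {
  msgs <- character(0)
  if (!"au" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'au' is required")
  }
  if (any(SummarizedExperiment::assay(object, "au") < 0, na.rm = TRUE)) {
    msgs <- c(msgs, "abundances must be >= 0")
  }
  needCol <- c("line_id", "genotype", "region", "timepoint", "replicate")
  missing <- setdiff(needCol, names(SummarizedExperiment::colData(object)))
  if (length(missing)) {
    msgs <- c(msgs, paste("colData lacks:", paste(missing, collapse = ", ")))
  }
  if (!length(msgs)) {
    gt <- SummarizedExperiment::colData(object)$genotype
    if (!all(gt %in% c("CTRL", "ALD"))) {
      msgs <- c(msgs, "genotype must be 'CTRL' or 'ALD'")
    }
    byLine <- split(as.character(gt),
                    SummarizedExperiment::colData(object)$line_id)
    if (any(vapply(byLine, function(g) length(unique(g)), 1L) > 1L)) {
      msgs <- c(msgs, "genotype must be constant within a line")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a LipidomicsExperiment
#'
#' @param au Numeric matrix species x samples (arbitrary units, >= 0).
#' @param rowData data.frame of species metadata (\code{class_code},
#'   \code{c_total}, \code{db_total}, \code{n_chains}); rownames or a
#'   \code{species} column give species names.
#' @param design data.frame study design, one row per sample, with columns
#'   \code{sample_id}, \code{line_id}, \code{genotype}, \code{region},
#'   \code{timepoint}, \code{replicate}.
#' @return A \linkS4class{LipidomicsExperiment}.
#' @export
LipidomicsExperiment <- function(au, rowData, design) {
  au <- as.matrix(au)
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if ("species" %in% names(rowData)) {
    rownames(au) <- rowData$species
    rownames(rowData) <- rowData$species
  }
  if ("sample_id" %in% names(design)) {
    colnames(au) <- design$sample_id
    rownames(design) <- design$sample_id
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(au = au),
    rowData = S4Vectors::DataFrame(rowData),
    colData = S4Vectors::DataFrame(design)
  )
  new("LipidomicsExperiment", se)
}

#' @describeIn LipidomicsExperiment The abundance matrix (assay
#'   \code{"au"}).
#' @param x,object A \code{LipidomicsExperiment}.
#' @export
abundances <- function(x) SummarizedExperiment::assay(x, "au")

#' @describeIn LipidomicsExperiment Species metadata as a data.frame.
#' @export
speciesData <- function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
}

#' @describeIn LipidomicsExperiment Study design as a data.frame.
#' @export
designTable <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

setMethod("show", "LipidomicsExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("LipidomicsExperiment:", nrow(object), "species x", ncol(object),
      "samples\n")
  cat("  classes:", length(unique(SummarizedExperiment::rowData(object)$class_code)),
      " lines:", length(unique(cd$line_id)),
      " timepoints:", paste(sort(unique(cd$timepoint)), collapse = ","), "\n")
  cat("  genotype:", paste(names(table(cd$genotype)), table(cd$genotype),
                           sep = ":", collapse = "  "), "\n")
})
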