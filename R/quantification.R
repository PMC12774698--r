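## Internal-standard semi-quantification into arbitrary units (A.U.) and
## aggregation of replicates to per-line profiles.

#' Normalize an analyte peak area to its internal standard
#'
#' Semi-quantification rule: the analyte response (peak area) divided by the
#' response of the class's internal standard in the same sample, scaled by
#' the spiked amount of that standard. The result is an arbitrary unit
#' (A.U.), invariant to any per-sample detector drift that multiplies both
#' areas equally.
#'
#' @param analyte_area Analyte peak area (>= 0). Vectorized.
#' @param is_area Internal-standard peak area in the same sample (> 0).
#' @param is_amount Spiked amount of the standard (nmol, > 0).
#' @return Semi-quantitative value in A.U.
#' @export
#' @examples
#' normalizeToStandard(100000, 100000, 2.0)  # 2.0 A.U.
normalizeToStandard <- function(analyte_area, is_area, is_amount) {
  if (any(is_area <= 0)) stop("internal-standard area must be > 0")
  if (any(is_amount <= 0)) stop("internal-standard amount must be > 0")
  if (any(analyte_area < 0)) stop("analyte area must be >= 0")
  analyte_area / is_area * is_amount
}

## Pick, per species, the single feature with smallest |ppm error|,
## preferring the polarity given first in `prefer`.
.consolidateAnnotations <- function(annotations, prefer_polarity = NULL) {
  ann <- annotations
  ord <- order(ann$species,
               if (is.null(prefer_polarity)) rep(0L, nrow(ann))
               else ifelse(ann$polarity == prefer_polarity, 0L, 1L),
               abs(ann$ppm_error))
  ann <- ann[ord, , drop = FALSE]
  ann[!duplicated(ann$species), , drop = FALSE]
}

#' Semi-quantify annotated features into an abundance table
#'
#' Converts annotated peak areas into A.U. per species and sample. Per
#' species, the single feature with the smallest absolute ppm error (in the
#' class's primary polarity where available) is used. Each class is
#' normalized against its configured internal standard: the standard's own
#' annotated feature, in the same polarity as the analyte feature, supplies
#' the per-sample reference areas. Classes whose standard has no annotated
#' feature in a usable polarity are dropped with a warning. Standard species
#' themselves are excluded from the analyte rows.
#'
#' @param annotations Annotation data.frame from \code{\link{matchFeatures}}.
#' @param features The annotated \linkS4class{FeatureTable}.
#' @param design Study design data.frame (one row per sample; columns
#'   \code{sample_id}, \code{line_id}, \code{genotype}, \code{region},
#'   \code{timepoint}, \code{replicate}). Samples are matched against the
#'   feature table's area columns.
#' @param mix Standards mix (\code{\link{readStandardsMix}}).
#' @param classes Class definition table supplying the class-to-standard
#'   mapping and primary polarity.
#' @return A \linkS4class{LipidomicsExperiment}.
#' @export
quantifyTable <- function(annotations, features, design, mix, classes) {
  areas <- featureAreas(features)
  if (!all(design$sample_id %in% colnames(areas))) {
    stop("design samples missing from feature table: ",
         paste(setdiff(design$sample_id, colnames(areas)), collapse = ", "))
  }
  areas <- areas[, design$sample_id, drop = FALSE]

  ## reference areas for each standard species, by polarity
  isAnn <- annotations[annotations$species %in% mix$species, , drop = FALSE]
  isAreas <- list()  # key "species|polarity" -> per-sample area vector
  for (sp in unique(isAnn$species)) {
    for (pol in unique(isAnn$polarity[isAnn$species == sp])) {
      sub <- isAnn[isAnn$species == sp & isAnn$polarity == pol, ,
                   drop = FALSE]
      best <- sub$feature_id[which.min(abs(sub$ppm_error))]
      isAreas[[paste(sp, pol, sep = "|")]] <- areas[best, ]
    }
  }

  primaryPolarity <- function(cl) {
    if (length(cl$adducts_pos[[1]])) "+" else "-"
  }

  analyte <- annotations[!(annotations$species %in% mix$species), ,
                         drop = FALSE]
  rows <- list()
  dropped <- character(0)
  for (code in unique(analyte$class_code)) {
    cl <- classes[match(code, classes$class_code), , drop = FALSE]
    std <- cl$internal_standard
    amt <- mix$nmol[match(std, mix$species)]
    if (is.na(amt)) {
      dropped <- c(dropped, code)
      next
    }
    sub <- .consolidateAnnotations(
      analyte[analyte$class_code == code, , drop = FALSE],
      prefer_polarity = primaryPolarity(cl)
    )
    for (i in seq_len(nrow(sub))) {
      ref <- isAreas[[paste(std, sub$polarity[i], sep = "|")]]
      if (is.null(ref)) {
        ## fall back to the standard's feature in its other polarity
        keys <- grep(paste0("^", gsub("([][()+*.^$\\\\])", "\\\\\\1", std),
                            "\\|"), names(isAreas), value = TRUE)
        if (length(keys)) ref <- isAreas[[keys[1]]]
      }
      if (is.null(ref)) {
        dropped <- c(dropped, code)
        rows <- rows[!vapply(rows, function(r) r$class_code == code, TRUE)]
        break
      }
      bad <- ref <= 0
      au <- rep(NA_real_, length(ref))
      au[!bad] <- normalizeToStandard(areas[sub$feature_id[i], !bad],
                                      ref[!bad], amt)
      rows[[length(rows) + 1L]] <- list(
        species = sub$species[i], class_code = code,
        c_total = NA, db_total = NA, au = au
      )
    }
  }
  if (length(dropped)) {
    warning("classes dropped (no usable internal-standard feature): ",
            paste(unique(dropped), collapse = ", "))
  }
  if (!length(rows)) stop("no quantifiable species")
  au <- do.call(rbind, lapply(rows, `[[`, "au"))
  speciesNames <- vapply(rows, `[[`, "", "species")
  parsed <- parseSpeciesName(speciesNames)
  rd <- data.frame(
    species = speciesNames,
    class_code = vapply(rows, `[[`, "", "class_code"),
    c_total = parsed$c_total, db_total = parsed$db_total,
    stringsAsFactors = FALSE
  )
  rd$n_chains <- classes$n_chains[match(rd$class_code, classes$class_code)]
  ord <- order(rd$class_code, rd$c_total, rd$db_total)
  LipidomicsExperiment(au[ord, , drop = FALSE], rd[ord, , drop = FALSE],
                       design)
}

#' Aggregate replicates to one profile per line and timepoint
#'
#' Element-wise median over the replicate samples of each (line, region,
#' timepoint) cell, the aggregation used for visualization-level profiles
#' ("median of three replicate samples per donor and timepoint"). For an
#' even number of replicates the median is the mean of the central pair.
#'
#' @param x A \linkS4class{LipidomicsExperiment} at replicate level.
#' @return A \linkS4class{LipidomicsExperiment} with one column per (line,
#'   region, timepoint); \code{replicate} is set to \code{NA}.
#' @export
medianByLine <- function(x) {
  au <- abundances(x)
  d <- designTable(x)
  key <- paste(d$line_id, d$region, d$timepoint, sep = "|")
  groups <- split(seq_len(ncol(au)), key)
  ## deterministic column order: region, timepoint, genotype, line
  first <- vapply(groups, `[`, 1L, 1L)
  ord <- order(d$region[first], d$timepoint[first], d$genotype[first],
               d$line_id[first])
  groups <- groups[ord]
  med <- vapply(groups, function(ix) {
    apply(au[, ix, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(au)))
  if (is.null(dim(med))) med <- matrix(med, nrow = nrow(au))
  first <- vapply(groups, `[`, 1L, 1L)
  newDesign <- data.frame(
    sample_id = paste(d$line_id[first], d$region[first],
                      sprintf("d%03d", d$timepoint[first]), sep = "_"),
    line_id = d$line_id[first], genotype = d$genotype[first],
    region = d$region[first], timepoint = d$timepoint[first],
    replicate = NA_integer_, stringsAsFactors = FALSE
  )
  colnames(med) <- newDesign$sample_id
  rownames(med) <- rownames(au)
  LipidomicsExperiment(med, speciesData(x), newDesign)
}
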