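## Candidate database construction and accurate-mass feature matching.

#' Build the candidate m/z database
#'
#' Expands every class into sum-composition species, converts each neutral
#' monoisotopic mass into the m/z of every adduct the class ionizes as, and
#' appends the internal standards (explicit compositions, e.g. deuterated
#' CE) using their class's adducts. Entries are sorted by m/z within
#' polarity for range queries.
#'
#' @param classes Class definition table (\code{\link{readClassDefinitions}}).
#' @param adducts Adduct table (\code{\link{readAdductTable}}).
#' @param standards Optional standards mix (\code{\link{readStandardsMix}});
#'   standards whose species name is not already in the expansion grid are
#'   added with their explicit formula, and all mix species are flagged
#'   \code{is_standard}.
#' @param constraint Unsaturation constraint passed to
#'   \code{\link{expandClass}}.
#' @return A \linkS4class{CandidateDB}.
#' @export
buildDatabase <- function(classes, adducts, standards = NULL,
                          constraint = defaultDbConstraint) {
  if (anyDuplicated(classes$class_code)) {
    stop("duplicate class codes in class definitions")
  }
  adductRow <- function(name) {
    i <- match(name, adducts$name)
    if (is.na(i)) stop("adduct not in adduct table: ", name)
    adducts[i, , drop = FALSE]
  }
  blocks <- vector("list", nrow(classes))
  for (i in seq_len(nrow(classes))) {
    cl <- classes[i, , drop = FALSE]
    sp <- expandClass(cl, constraint)
    if (!nrow(sp)) next
    anames <- c(cl$adducts_pos[[1]], cl$adducts_neg[[1]])
    sub <- vector("list", length(anames))
    for (j in seq_along(anames)) {
      ad <- adductRow(anames[j])
      sub[[j]] <- data.frame(
        species = sp$species, class_code = sp$class_code,
        c_total = sp$c_total, db_total = sp$db_total,
        n_chains = sp$n_chains, adduct = ad$name, polarity = ad$polarity,
        mz = adductMz(sp$neutral_mass, ad), neutral_mass = sp$neutral_mass,
        is_standard = FALSE, stringsAsFactors = FALSE
      )
    }
    blocks[[i]] <- do.call(rbind, sub)
  }
  emptyEntries <- data.frame(
    species = character(0), class_code = character(0),
    c_total = integer(0), db_total = integer(0), n_chains = integer(0),
    adduct = character(0), polarity = character(0), mz = numeric(0),
    neutral_mass = numeric(0), is_standard = logical(0),
    stringsAsFactors = FALSE
  )
  blocks <- blocks[!vapply(blocks, is.null, TRUE)]
  entries <- if (length(blocks)) do.call(rbind, blocks) else emptyEntries
  if (!is.null(standards)) {
    ## standards for classes outside this class set are irrelevant here
    standards <- standards[standards$class_code %in% classes$class_code, ,
                           drop = FALSE]
    extra <- standards[!(standards$species %in% entries$species), ,
                       drop = FALSE]
    if (nrow(extra)) {
      sub <- vector("list", nrow(extra))
      for (k in seq_len(nrow(extra))) {
        cl <- classes[match(extra$class_code[k], classes$class_code), ,
                      drop = FALSE]
        if (!nrow(cl) || is.na(cl$class_code)) {
          stop("standard ", extra$species[k], " references unknown class ",
               extra$class_code[k])
        }
        mass <- monoisotopicMass(parseFormula(extra$formula[k]))
        anames <- c(cl$adducts_pos[[1]], cl$adducts_neg[[1]])
        rows <- vector("list", length(anames))
        for (j in seq_along(anames)) {
          ad <- adductRow(anames[j])
          rows[[j]] <- data.frame(
            species = extra$species[k], class_code = cl$class_code,
            c_total = NA_integer_, db_total = NA_integer_,
            n_chains = cl$n_chains, adduct = ad$name, polarity = ad$polarity,
            mz = adductMz(mass, ad), neutral_mass = mass,
            is_standard = TRUE, stringsAsFactors = FALSE
          )
        }
        sub[[k]] <- do.call(rbind, rows)
      }
      entries <- rbind(entries, do.call(rbind, sub))
    }
    entries$is_standard <- entries$is_standard |
      entries$species %in% standards$species
  }
  entries <- entries[order(entries$polarity, entries$mz), , drop = FALSE]
  rownames(entries) <- NULL
  new("CandidateDB", entries = entries)
}

#' Signed parts-per-million mass error
#'
#' @param observed Observed m/z (Th).
#' @param theoretical Theoretical m/z (Th), > 0.
#' @return \code{(observed - theoretical) / theoretical * 1e6}.
#' @export
#' @examples
#' ppmError(500.0025, 500.0)  # +5 ppm
ppmError <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0")
  (observed - theoretical) / theoretical * 1e6
}

#' Range-query the candidate database
#'
#' Returns every entry of the given polarity within \code{tol_ppm} of
#' \code{mz}, by binary search on the sorted index (equivalent to a linear
#' scan by construction).
#'
#' @param db A \linkS4class{CandidateDB}.
#' @param mz Query m/z (single value).
#' @param polarity \code{"+"} or \code{"-"}.
#' @param tol_ppm Tolerance in parts per million (> 0).
#' @return The matching rows of \code{dbEntries(db)}.
#' @export
mzQuery <- function(db, mz, polarity, tol_ppm = 5) {
  stopifnot(tol_ppm > 0, length(mz) == 1L)
  e <- db@entries
  idx <- which(e$polarity == polarity)
  if (!length(idx)) return(e[integer(0), , drop = FALSE])
  mzs <- e$mz[idx]
  lo <- mz * (1 - tol_ppm * 1e-6)
  hi <- mz * (1 + tol_ppm * 1e-6)
  i1 <- findInterval(lo, mzs, left.open = TRUE) + 1L
  i2 <- findInterval(hi, mzs)
  if (i2 < i1) return(e[integer(0), , drop = FALSE])
  e[idx[i1:i2], , drop = FALSE]
}

#' Match features to candidates by accurate mass
#'
#' Each feature is assigned the candidate of matching polarity with the
#' smallest absolute ppm error within \code{tol_ppm} (ties broken by
#' \code{(class_code, adduct)} lexicographic order); the number of
#' candidates within tolerance is recorded as \code{ambiguity_count}.
#' Optionally candidates are first gated by per-class retention-time
#' windows.
#'
#' @param features A \linkS4class{FeatureTable}.
#' @param db A \linkS4class{CandidateDB}.
#' @param tol_ppm Mass tolerance in ppm (default 5, matching an Orbitrap
#'   operated at high resolution).
#' @param rt_windows Optional data.frame with columns \code{class_code},
#'   \code{rt_min}, \code{rt_max}; candidates of a listed class are only
#'   eligible if the feature RT is inside the window.
#' @return List with \code{annotations} (data.frame: \code{feature_id},
#'   \code{species}, \code{class_code}, \code{adduct}, \code{polarity},
#'   \code{theoretical_mz}, \code{ppm_error}, \code{ambiguity_count},
#'   \code{rt_pass}, \code{is_standard}) and \code{unmatched} (feature ids).
#' @export
matchFeatures <- function(features, db, tol_ppm = 5, rt_windows = NULL) {
  stopifnot(tol_ppm > 0)
  info <- featureInfo(features)
  res <- vector("list", nrow(info))
  unmatched <- character(0)
  for (i in seq_len(nrow(info))) {
    cand <- mzQuery(db, info$mz[i], info$polarity[i], tol_ppm)
    rt_pass <- NA
    if (!is.null(rt_windows) && nrow(cand)) {
      w <- rt_windows[match(cand$class_code, rt_windows$class_code), ,
                      drop = FALSE]
      inWin <- is.na(w$rt_min) | is.na(info$rt[i]) |
        (info$rt[i] >= w$rt_min & info$rt[i] <= w$rt_max)
      cand <- cand[inWin, , drop = FALSE]
      rt_pass <- TRUE
    }
    if (!nrow(cand)) {
      unmatched <- c(unmatched, info$feature_id[i])
      next
    }
    err <- ppmError(info$mz[i], cand$mz)
    ord <- order(abs(err), cand$class_code, cand$adduct)
    best <- ord[1L]
    res[[i]] <- data.frame(
      feature_id = info$feature_id[i],
      species = cand$species[best],
      class_code = cand$class_code[best],
      adduct = cand$adduct[best],
      polarity = info$polarity[i],
      theoretical_mz = cand$mz[best],
      ppm_error = err[best],
      ambiguity_count = nrow(cand),
      rt_pass = rt_pass,
      is_standard = cand$is_standard[best],
      stringsAsFactors = FALSE
    )
  }
  ann <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(ann)) {
    ann <- data.frame(feature_id = character(0), species = character(0),
                      class_code = character(0), adduct = character(0),
                      polarity = character(0), theoretical_mz = numeric(0),
                      ppm_error = numeric(0), ambiguity_count = integer(0),
                      rt_pass = logical(0), is_standard = logical(0),
                      stringsAsFactors = FALSE)
  }
  rownames(ann) <- NULL
  list(annotations = ann, unmatched = unmatched)
}
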