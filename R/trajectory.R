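## Descriptive trajectory analyses: class Z-scores, log2 fold-change curves
## over chain length / unsaturation with LOESS smoothing, and PCA.

#' Log-transform abundances with a pseudo-value for zeros
#'
#' Zeros are replaced per species by half the smallest nonzero value of that
#' species before taking logs; all-zero species stay at zero abundance and
#' are reported in the \code{"flagged"} attribute.
#'
#' @param au Species x sample abundance matrix.
#' @param base Log base (default e).
#' @return Log matrix with attribute \code{"flagged"} (all-zero species).
#' @export
logAbundance <- function(au, base = exp(1)) {
  out <- au
  flagged <- character(0)
  for (i in seq_len(nrow(au))) {
    v <- au[i, ]
    nz <- v[!is.na(v) & v > 0]
    if (!length(nz)) {
      flagged <- c(flagged, rownames(au)[i])
      out[i, ] <- NA_real_
      next
    }
    v[!is.na(v) & v == 0] <- min(nz) / 2
    out[i, ] <- log(v, base = base)
  }
  structure(out, flagged = flagged)
}

#' Class-level abundance and Z-score trajectories
#'
#' Sums member species per class into a class x sample abundance matrix and
#' Z-scores each class row across all cells using the sample standard
#' deviation (n - 1). Constant (or all-zero) classes get a zero row and are
#' flagged.
#'
#' @param x A \linkS4class{LipidomicsExperiment}, typically at line-median
#'   level.
#' @return List with \code{abundance} (class x sample), \code{z} (same
#'   shape), \code{design} (the sample metadata), and \code{flagged}
#'   (classes with constant abundance).
#' @export
classZScores <- function(x) {
  au <- abundances(x)
  cls <- speciesData(x)$class_code
  ab <- rowsum(au, cls)
  z <- ab
  flagged <- character(0)
  for (i in seq_len(nrow(ab))) {
    v <- ab[i, ]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) {
      z[i, ] <- 0
      flagged <- c(flagged, rownames(ab)[i])
    } else {
      z[i, ] <- (v - mean(v)) / s
    }
  }
  list(abundance = ab, z = z, design = designTable(x), flagged = flagged)
}

## tricube kernel on |u| < 1
.tricube <- function(u) {
  w <- (1 - pmin(abs(u), 1)^3)^3
  w[abs(u) >= 1] <- 0
  w
}

#' LOESS smoothing (locally weighted polynomial regression)
#'
#' Cleveland-style local regression: at each evaluation point the
#' \code{floor(span * n)} nearest observations get tricube weights scaled by
#' the distance to the furthest neighbour, and a weighted polynomial of the
#' given degree is fitted. Deterministic; agrees with the classical
#' reference implementation on interior points and reproduces polynomials of
#' degree <= \code{degree} exactly.
#'
#' @param x,y Numeric vectors of equal length; at least
#'   \code{max(4, degree + 2)} distinct x values.
#' @param span Fraction of points in each local neighbourhood (0 < span <=
#'   1; values > 1 give one neighbourhood of all points with inflated
#'   bandwidth). Default 0.75.
#' @param degree Local polynomial degree (0, 1 or 2). Default 2.
#' @param eval_x Evaluation grid; defaults to the sorted unique \code{x}.
#' @return List with \code{x} (grid) and \code{fitted}.
#' @export
loessSmooth <- function(x, y, span = 0.75, degree = 2, eval_x = NULL) {
  stopifnot(length(x) == length(y), span > 0, degree %in% 0:2)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (length(unique(x)) < max(4, degree + 2)) {
    stop("need at least ", max(4, degree + 2), " distinct x values")
  }
  if (is.null(eval_x)) eval_x <- sort(unique(x))
  q <- max(degree + 1, min(n, floor(n * min(span, 1))))
  fitted <- numeric(length(eval_x))
  for (k in seq_along(eval_x)) {
    d <- abs(x - eval_x[k])
    h <- sort(d, partial = q)[q]
    if (span > 1) h <- h * span^(1 / degree)
    if (h <= 0) {
      fitted[k] <- mean(y[d == 0])
      next
    }
    w <- .tricube(d / h)
    use <- w > 0
    X <- outer(x[use] - eval_x[k], 0:degree, `^`)
    fit <- stats::lm.wfit(X, y[use], w[use])
    fitted[k] <- fit$coefficients[1L]
  }
  list(x = eval_x, fitted = fitted)
}

#' Fold-change curves over a chain property
#'
#' Per-species log2 fold changes between two sample groups, computed on
#' line-median abundances, binned by the class's chain count and either
#' total carbons or total double bonds, with a LOESS fit through the per-bin
#' means. This is the chain-length / unsaturation signature view (e.g.
#' timepoints relative to day 50, or ALD relative to CTRL). Classes with
#' four chains are excluded from the 1/2/3-chain curves.
#'
#' @param x A \linkS4class{LipidomicsExperiment}.
#' @param property \code{"c_total"} (total acyl carbons) or
#'   \code{"db_total"} (total double bonds).
#' @param contrast Character vector \code{c(column, reference, comparison)},
#'   e.g. \code{c("timepoint", "50", "100")} or
#'   \code{c("genotype", "CTRL", "ALD")}.
#' @param span,degree LOESS parameters (defaults 0.75, 2).
#' @param line_median Aggregate to line medians first (default TRUE).
#' @return List with \code{curves} (data.frame: \code{n_chains}, \code{x},
#'   \code{mean_log2fc}, \code{n_species}, \code{loess_fc},
#'   \code{contrast}), \code{species} (per-species log2 FC), and
#'   \code{excluded} (species with a nonpositive group mean).
#' @export
fcByChainProperty <- function(x, property = c("c_total", "db_total"),
                              contrast, span = 0.75, degree = 2,
                              line_median = TRUE) {
  property <- match.arg(property)
  stopifnot(length(contrast) == 3L)
  if (line_median) x <- medianByLine(x)
  d <- designTable(x)
  colv <- as.character(d[[contrast[1L]]])
  refIdx <- colv == contrast[2L]
  cmpIdx <- colv == contrast[3L]
  if (!any(refIdx) || !any(cmpIdx)) {
    stop("empty contrast group for ", contrast[1L])
  }
  au <- abundances(x)
  meanRef <- rowMeans(au[, refIdx, drop = FALSE])
  meanCmp <- rowMeans(au[, cmpIdx, drop = FALSE])
  meta <- speciesData(x)
  ok <- meanRef > 0 & meanCmp > 0 & meta$n_chains %in% 1:3
  excluded <- rownames(au)[meanRef <= 0 | meanCmp <= 0]
  sp <- data.frame(
    species = rownames(au)[ok],
    n_chains = meta$n_chains[ok],
    x = meta[[property]][ok],
    log2fc = log2(meanCmp[ok] / meanRef[ok]),
    stringsAsFactors = FALSE
  )
  label <- paste(contrast[3L], "vs", contrast[2L])
  curves <- list()
  for (nc in sort(unique(sp$n_chains))) {
    sub <- sp[sp$n_chains == nc, , drop = FALSE]
    agg <- stats::aggregate(log2fc ~ x, data = sub, FUN = mean)
    agg$n_species <- as.integer(table(factor(sub$x, levels = agg$x)))
    if (nrow(agg) >= max(4, degree + 2)) {
      fit <- loessSmooth(agg$x, agg$log2fc, span = span, degree = degree)
      agg$loess_fc <- fit$fitted[match(agg$x, fit$x)]
    } else {
      agg$loess_fc <- NA_real_
    }
    curves[[length(curves) + 1L]] <- data.frame(
      n_chains = nc, x = agg$x, mean_log2fc = agg$log2fc,
      n_species = agg$n_species, loess_fc = agg$loess_fc,
      contrast = label, stringsAsFactors = FALSE
    )
  }
  list(curves = do.call(rbind, curves), species = sp, excluded = excluded)
}

#' PCA of lipidomic profiles
#'
#' Principal component analysis of samples on log-transformed,
#' species-centered abundances (optionally unit-scaled per species).
#'
#' @param x A \linkS4class{LipidomicsExperiment}.
#' @param log Log-transform first (default TRUE, with the zero pseudo-value
#'   policy of \code{\link{logAbundance}}).
#' @param scale Scale species to unit variance (correlation PCA); default
#'   FALSE (covariance PCA on log values).
#' @return List with \code{scores} (samples x components),
#'   \code{explained} (variance fractions, non-increasing), \code{loadings},
#'   \code{sdev}, and \code{design}.
#' @export
pcaScores <- function(x, log = TRUE, scale = FALSE) {
  au <- abundances(x)
  if (nrow(au) < 2L || ncol(au) < 2L) stop("need >= 2 species and samples")
  m <- if (log) logAbundance(au) else au
  m <- m[rowSums(is.na(m)) == 0, , drop = FALSE]
  m <- m[apply(m, 1L, stats::sd) > 0 | !scale, , drop = FALSE]
  if (!nrow(m)) stop("no non-constant species to analyse")
  p <- stats::prcomp(t(m), center = TRUE, scale. = scale)
  list(scores = p$x, explained = p$sdev^2 / sum(p$sdev^2),
       loadings = p$rotation, sdev = p$sdev, design = designTable(x))
}
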