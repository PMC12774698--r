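## Per-lipid mixed-effects differential testing with FDR control, and the
## volcano / bubble summary tables.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; order-preserving.
#' Thin wrapper over \code{stats::p.adjust(method = "BH")} kept as the
#' package's single FDR entry point (the correction family is all species
#' within one contrast).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted values, same order; empty in, empty out.
#' @export
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03))
bhFdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fit the per-lipid mixed-effects model
#'
#' Models log abundance with a fixed genotype effect and a random intercept
#' per donor line (capturing within-line replicate correlation). In
#' \code{"per_timepoint"} mode the supplied data are one timepoint and the
#' model is \code{log(y) ~ genotype + (1 | line)}; in \code{"overall"} mode
#' it is \code{log(y) ~ genotype + factor(timepoint) + (1 | line)}, the
#' single overall group difference across all timepoints. Estimation is
#' REML; the genotype effect (positive = higher in ALD) is tested with a
#' Satterthwaite t test by default (\code{method = "wald"} gives the normal
#' approximation instead, which is anti-conservative at a dozen lines).
#' When only one observation per line is present (line-median data in
#' per-timepoint mode) the random intercept is not identifiable and the
#' model reduces to ordinary least squares, flagged \code{"fixed_only"};
#' the same fallback is used if the mixed fit fails. Singular (zero line
#' variance) fits are kept and flagged \code{"singular"}.
#'
#' @param values Positive abundance values, one per sample.
#' @param design data.frame aligned with \code{values}; columns
#'   \code{line_id}, \code{genotype}, and \code{timepoint} (for
#'   \code{"overall"}).
#' @param mode \code{"per_timepoint"} or \code{"overall"}.
#' @param method \code{"satterthwaite"} (default) or \code{"wald"}.
#' @return List: \code{effect} (natural-log scale), \code{se}, \code{p},
#'   \code{df}, \code{n_obs}, \code{flag} (\code{"ok"}, \code{"singular"} or
#'   \code{"fixed_only"}).
#' @export
fitLipidLmm <- function(values, design,
                        mode = c("per_timepoint", "overall"),
                        method = c("satterthwaite", "wald")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(length(values) == nrow(design), all(values > 0))
  df <- data.frame(
    logy = log(values),
    genotype = factor(design$genotype, levels = c("CTRL", "ALD")),
    line_id = factor(design$line_id),
    stringsAsFactors = FALSE
  )
  if (mode == "overall") df$tp <- factor(design$timepoint)
  for (g in c("CTRL", "ALD")) {
    if (length(unique(df$line_id[df$genotype == g])) < 2L) {
      stop("need >= 2 lines per genotype group")
    }
  }
  fixedForm <- if (mode == "overall") logy ~ genotype + tp else logy ~ genotype
  perLine <- max(table(df$line_id)) == 1L
  fit <- NULL
  flag <- "ok"
  if (!perLine) {
    mixedForm <- stats::update(fixedForm, . ~ . + (1 | line_id))
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(mixedForm, data = df, REML = TRUE)),
      error = function(e) NULL
    )
  }
  if (!is.null(fit)) {
    if (lme4::isSingular(fit, tol = 1e-4)) flag <- "singular"
    co <- stats::coef(summary(fit))["genotypeALD", ]
    est <- co[["Estimate"]]; se <- co[["Std. Error"]]; dfree <- co[["df"]]
    p <- if (method == "satterthwaite") co[["Pr(>|t|)"]]
         else 2 * stats::pnorm(-abs(est / se))
  } else {
    flag <- "fixed_only"
    lmfit <- stats::lm(fixedForm, data = df)
    co <- stats::coef(summary(lmfit))["genotypeALD", ]
    est <- co[["Estimate"]]; se <- co[["Std. Error"]]
    dfree <- lmfit$df.residual
    p <- if (method == "wald") 2 * stats::pnorm(-abs(est / se))
         else co[["Pr(>|t|)"]]
  }
  list(effect = est, se = se, p = p, df = dfree, n_obs = nrow(df),
       flag = flag)
}

#' Differential testing of every lipid species
#'
#' Applies \code{\link{fitLipidLmm}} to each species, either once per
#' timepoint (\code{mode = "per_timepoint"}) or once across all timepoints
#' (\code{mode = "overall"}), and BH-adjusts p-values per contrast across
#' species. Effects are reported on the natural-log scale and as log2 fold
#' changes; positive = higher in ALD. Zeros are handled with the per-species
#' pseudo-value policy of \code{\link{logAbundance}}; all-zero species are
#' skipped.
#'
#' @param x A \linkS4class{LipidomicsExperiment} at replicate level.
#' @param mode \code{"per_timepoint"} (default) or \code{"overall"}.
#' @param data_level \code{"replicate"} (default; random intercept per
#'   line) or \code{"line_median"} (aggregate first).
#' @param method Inference method passed to \code{\link{fitLipidLmm}}.
#' @param timepoints Timepoints to test in per-timepoint mode (default all).
#' @return data.frame with one row per (species, contrast): \code{species},
#'   \code{class_code}, \code{c_total}, \code{db_total}, \code{contrast},
#'   \code{effect_ln}, \code{log2_fc}, \code{se}, \code{p}, \code{fdr},
#'   \code{n_obs}, \code{mode}, \code{fit_flag}.
#' @export
testDifferential <- function(x, mode = c("per_timepoint", "overall"),
                             data_level = c("replicate", "line_median"),
                             method = c("satterthwaite", "wald"),
                             timepoints = NULL) {
  mode <- match.arg(mode)
  data_level <- match.arg(data_level)
  method <- match.arg(method)
  if (data_level == "line_median") x <- medianByLine(x)
  au <- abundances(x)
  lau <- logAbundance(au)        # applies the zero pseudo-value policy
  au <- exp(lau)                 # positive values, zeros imputed
  d <- designTable(x)
  meta <- speciesData(x)
  skip <- attr(lau, "flagged")
  contrasts <- if (mode == "overall") list(overall = seq_len(nrow(d)))
  else {
    tps <- if (is.null(timepoints)) sort(unique(d$timepoint)) else timepoints
    stats::setNames(lapply(tps, function(tp) which(d$timepoint == tp)),
                    paste0("d", tps))
  }
  out <- list()
  for (lbl in names(contrasts)) {
    idx <- contrasts[[lbl]]
    rows <- lapply(setdiff(rownames(au), skip), function(sp) {
      fit <- fitLipidLmm(au[sp, idx], d[idx, , drop = FALSE],
                         mode = mode, method = method)
      data.frame(
        species = sp,
        class_code = meta$class_code[match(sp, rownames(au))],
        c_total = meta$c_total[match(sp, rownames(au))],
        db_total = meta$db_total[match(sp, rownames(au))],
        contrast = lbl, effect_ln = fit$effect,
        log2_fc = fit$effect / log(2), se = fit$se, p = fit$p,
        n_obs = fit$n_obs, mode = mode, fit_flag = fit$flag,
        stringsAsFactors = FALSE
      )
    })
    block <- do.call(rbind, rows)
    block$fdr <- bhFdr(block$p)
    out[[lbl]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("species", "class_code", "c_total", "db_total", "contrast",
          "effect_ln", "log2_fc", "se", "p", "fdr", "n_obs", "mode",
          "fit_flag")]
}

#' Volcano summary table
#'
#' One row per (species, contrast) with the log2 fold change and
#' \eqn{-\log_{10} p}, class code attached for colouring.
#'
#' @param results Output of \code{\link{testDifferential}}.
#' @return data.frame: \code{species}, \code{class_code}, \code{contrast},
#'   \code{log2_fc}, \code{neg_log10_p}, \code{fdr}.
#' @export
volcanoTable <- function(results) {
  data.frame(
    species = results$species, class_code = results$class_code,
    contrast = results$contrast, log2_fc = results$log2_fc,
    neg_log10_p = -log10(results$p), fdr = results$fdr,
    stringsAsFactors = FALSE
  )
}

#' Bubble summary table over chain length and unsaturation
#'
#' Per-(class, C, db) rows of log2 fold change and \eqn{-\log_{10} p} for
#' the requested classes at one contrast, the view relating effect size to
#' acyl chain length and double-bond count.
#'
#' @param results Output of \code{\link{testDifferential}}.
#' @param species_meta Species metadata (\code{\link{speciesData}}) defining
#'   the known class universe.
#' @param classes Classes to include (default CE, PC, TG).
#' @param contrast Contrast label to show (default the last one present).
#' @return data.frame: \code{class_code}, \code{c_total}, \code{db_total},
#'   \code{log2_fc}, \code{neg_log10_p}, \code{fdr}.
#' @export
bubbleTable <- function(results, species_meta,
                        classes = c("CE", "PC", "TG"), contrast = NULL) {
  unknown <- setdiff(classes, unique(species_meta$class_code))
  if (length(unknown)) {
    stop("unknown class(es) requested: ", paste(unknown, collapse = ", "))
  }
  if (is.null(contrast)) contrast <- utils::tail(results$contrast, 1L)
  sub <- results[results$contrast == contrast &
                   results$class_code %in% classes, , drop = FALSE]
  empty <- setdiff(classes, unique(sub$class_code))
  if (length(empty)) {
    warning("no tested species for class(es): ",
            paste(empty, collapse = ", "))
  }
  data.frame(
    class_code = sub$class_code, c_total = sub$c_total,
    db_total = sub$db_total, log2_fc = sub$log2_fc,
    neg_log10_p = -log10(sub$p), fdr = sub$fdr,
    stringsAsFactors = FALSE
  )
}
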