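## Seeded synthetic-data generators emulating the study design: control vs
## ALD donor lines, longitudinal timepoints, lognormal noise with per-line
## random intercepts, and a chain-length-dependent ALD enrichment effect
## (VLCFA signature). The generators carry a truth object sufficient to
## recompute every expected value.

#' Simulation parameters
#'
#' Defaults mirror the study design: 3 control and 9 ALD donor lines, 3
#' replicate samples per line and timepoint, cortical-organoid timepoints
#' (days 50, 100, 150, 200; use \code{timepoints = c(50, 100)} with
#' \code{region = "hSO"} for the spinal-cord design). Noise is lognormal:
#' additive Normal on the log scale, matching the mixed model's
#' assumptions, with a per-(line, species) random intercept of SD
#' \code{sigma_line} and residual SD \code{sigma_e} (natural-log scale).
#' The ALD enrichment is a hinge in total chain length: log2 fold change
#' \code{vlcfa_effect * max(0, C - C0)} with the carbon threshold \code{C0}
#' at 26, 46 and 62 for classes with 1, 2 and 3 chains.
#'
#' @param n_control_lines,n_ald_lines Donor lines per genotype (3, 9).
#' @param replicates Replicate samples per line and timepoint (3).
#' @param timepoints Days (default \code{c(50, 100, 150, 200)}).
#' @param region \code{"hCO"} or \code{"hSO"}.
#' @param sigma_line Line random-intercept SD, natural-log scale (0.2).
#' @param sigma_e Residual SD, natural-log scale (0.3).
#' @param vlcfa_effect Genotype log2 fold change per carbon above the
#'   threshold (0.1).
#' @param c0 Named carbon thresholds per chain count (1, 2, 3 chains).
#' @param baseline_meanlog,baseline_sdlog Species baseline distribution on
#'   the natural-log A.U. scale.
#' @param trajectories Optional class x timepoint matrix of log2
#'   multiplicative timepoint profiles; default shapes follow the organoid
#'   maturation trends (see \code{\link{defaultClassTrajectories}}).
#' @return Named list of parameters.
#' @export
simulationParams <- function(n_control_lines = 3, n_ald_lines = 9,
                             replicates = 3,
                             timepoints = c(50, 100, 150, 200),
                             region = "hCO",
                             sigma_line = 0.2, sigma_e = 0.3,
                             vlcfa_effect = 0.1,
                             c0 = c(`1` = 26, `2` = 46, `3` = 62),
                             baseline_meanlog = log(0.2),
                             baseline_sdlog = 1,
                             trajectories = NULL) {
  stopifnot(n_control_lines >= 1, n_ald_lines >= 1, replicates >= 1,
            sigma_line >= 0, sigma_e >= 0, length(timepoints) >= 1)
  list(n_control_lines = n_control_lines, n_ald_lines = n_ald_lines,
       replicates = replicates, timepoints = sort(unique(timepoints)),
       region = region, sigma_line = sigma_line, sigma_e = sigma_e,
       vlcfa_effect = vlcfa_effect, c0 = c0,
       baseline_meanlog = baseline_meanlog,
       baseline_sdlog = baseline_sdlog, trajectories = trajectories)
}

#' Default class trajectory shapes
#'
#' Qualitative log2 timepoint profiles per class, following the maturation
#' trends of an organoid lipidome: membrane glycerophospholipids and
#' neutral storage lipids (PC, PE, ether forms, TG, DG) start high and
#' decline; lysophospholipids, sphingomyelins and ceramides rise at
#' intermediate days; gangliosides, sulfatides and di-hexosylceramides rise
#' late. Config-driven, not a quantitative claim. Shapes are defined on
#' four anchor stages and linearly interpolated to the requested number of
#' timepoints.
#'
#' @param class_codes Character vector of class codes.
#' @param timepoints Numeric timepoints (days).
#' @return Matrix class x timepoint of log2 offsets (0 for classes without
#'   a listed trend).
#' @export
defaultClassTrajectories <- function(class_codes, timepoints) {
  shapes <- list(
    early = c(0.5, 0, -0.5, -0.7),
    mid = c(-0.5, 0.3, 0.5, 0.5),
    late = c(-0.7, -0.2, 0.5, 0.7)
  )
  groupOf <- function(code) {
    if (code %in% c("PC", "PC[O]", "PE", "PE[O]", "PE[P]", "TG", "DG"))
      "early"
    else if (code %in% c("LPC", "LPE", "LPE[O]", "LPE[P]", "LPA", "LPG",
                         "LPI", "FA", "SM[d]", "SM[t]", "Cer[d]", "Cer[t]"))
      "mid"
    else if (code %in% c("GM1[d]", "GM2[d]", "GM3[d]", "SM4[d]", "SM4[t]",
                         "HexCer[d]", "Hex2Cer[d]"))
      "late"
    else NA_character_
  }
  tp <- sort(unique(timepoints))
  out <- matrix(0, nrow = length(class_codes), ncol = length(tp),
                dimnames = list(class_codes, as.character(tp)))
  u <- if (length(tp) == 1L) 0 else seq(0, 1, length.out = length(tp))
  for (i in seq_along(class_codes)) {
    g <- groupOf(class_codes[i])
    if (is.na(g)) next
    out[i, ] <- if (length(tp) == 1L) shapes[[g]][1L]
    else stats::approx(seq(0, 1, length.out = 4L), shapes[[g]], xout = u)$y
  }
  out
}

.makeDesign <- function(params) {
  lines <- c(sprintf("CTRL%02d", seq_len(params$n_control_lines)),
             sprintf("ALD%02d", seq_len(params$n_ald_lines)))
  genotype <- c(rep("CTRL", params$n_control_lines),
                rep("ALD", params$n_ald_lines))
  grid <- expand.grid(replicate = seq_len(params$replicates),
                      timepoint = params$timepoints,
                      line = seq_along(lines), KEEP.OUT.ATTRS = FALSE)
  data.frame(
    sample_id = sprintf("%s_%s_d%03d_r%d", lines[grid$line], params$region,
                        grid$timepoint, grid$replicate),
    line_id = lines[grid$line], genotype = genotype[grid$line],
    region = params$region, timepoint = grid$timepoint,
    replicate = grid$replicate, stringsAsFactors = FALSE
  )
}

#' Simulate a longitudinal lipidomics study with known truth
#'
#' Generates a species x sample abundance table under the model
#' \deqn{\log y = baseline(species) + \ln 2 \, [traj(class, t) +
#'   fc(species) \cdot 1_{ALD}] + b_{line,species} + \varepsilon,}
#' with \eqn{b \sim N(0, \sigma_{line}^2)},
#' \eqn{\varepsilon \sim N(0, \sigma_e^2)} and the genotype log2 fold
#' change \eqn{fc = vlcfa\_effect \cdot \max(0, C - C_0(chains))}. Random
#' intercepts are drawn independently per (line, species) so that each
#' lipid's mixed model sees its own line effects. All draws come from one
#' seeded generator in a fixed order (baselines, intercepts, residuals), so
#' the same seed reproduces the table bitwise.
#'
#' @param params \code{\link{simulationParams}}.
#' @param classes Class definition table; defaults to the shipped set.
#' @param seed Integer seed.
#' @return List with \code{experiment} (a
#'   \linkS4class{LipidomicsExperiment}) and \code{truth} (species table
#'   with true log2 genotype effects, the trajectory matrix, baselines,
#'   per-(line, species) intercepts, params and seed).
#' @export
simulateStudy <- function(params = simulationParams(),
                          classes = readClassDefinitions(), seed = 1) {
  set.seed(seed)
  species <- do.call(rbind, lapply(seq_len(nrow(classes)), function(i) {
    expandClass(classes[i, , drop = FALSE])
  }))
  design <- .makeDesign(params)
  nsp <- nrow(species)
  lines <- unique(design$line_id)
  traj <- params$trajectories
  if (is.null(traj)) {
    traj <- defaultClassTrajectories(classes$class_code, params$timepoints)
  }
  c0 <- params$c0[as.character(species$n_chains)]
  fc_log2 <- ifelse(is.na(c0), 0,
                    params$vlcfa_effect * pmax(0, species$c_total - c0))
  baseline <- stats::rnorm(nsp, params$baseline_meanlog,
                           params$baseline_sdlog)
  b <- matrix(stats::rnorm(nsp * length(lines), 0, params$sigma_line),
              nrow = nsp, dimnames = list(species$species, lines))
  ln2 <- log(2)
  au <- matrix(0, nrow = nsp, ncol = nrow(design),
               dimnames = list(species$species, design$sample_id))
  trajClass <- traj[species$class_code, , drop = FALSE]
  for (j in seq_len(nrow(design))) {
    mu <- baseline +
      ln2 * trajClass[, as.character(design$timepoint[j])] +
      ln2 * fc_log2 * (design$genotype[j] == "ALD") +
      b[, design$line_id[j]]
    eps <- stats::rnorm(nsp, 0, params$sigma_e)
    au[, j] <- exp(mu + eps)
  }
  rowData <- data.frame(species = species$species,
                        class_code = species$class_code,
                        c_total = species$c_total,
                        db_total = species$db_total,
                        n_chains = species$n_chains,
                        stringsAsFactors = FALSE)
  truth_species <- cbind(rowData,
                         effect_log2 = fc_log2,
                         baseline_ln = baseline)
  list(
    experiment = LipidomicsExperiment(au, rowData, design),
    truth = list(species = truth_species, trajectory_log2 = traj,
                 line_intercepts = b, params = params, seed = seed)
  )
}

#' Simulate replicate values for a single lipid
#'
#' One-lipid, one-timepoint generator used for estimator-recovery and null
#' calibration checks: \eqn{\log y = \beta \cdot 1_{ALD} + b_{line} +
#' \varepsilon} with line intercepts of SD \code{sigma_line} and residuals
#' of SD \code{sigma_e}.
#'
#' @param beta_ln Genotype effect, natural-log scale.
#' @param n_control,n_ald Lines per group.
#' @param replicates Replicates per line.
#' @param sigma_line,sigma_e Random-intercept and residual SDs.
#' @param seed Integer seed.
#' @return List with \code{values} (positive abundances) and \code{design}.
#' @export
simulateLipidValues <- function(beta_ln = 1, n_control = 3, n_ald = 9,
                                replicates = 3, sigma_line = 0.2,
                                sigma_e = 0.3, seed = 1) {
  set.seed(seed)
  lines <- c(sprintf("CTRL%02d", seq_len(n_control)),
             sprintf("ALD%02d", seq_len(n_ald)))
  genotype <- rep(c("CTRL", "ALD"), c(n_control, n_ald))
  design <- data.frame(
    line_id = rep(lines, each = replicates),
    genotype = rep(genotype, each = replicates),
    timepoint = 50L, stringsAsFactors = FALSE
  )
  b <- stats::rnorm(length(lines), 0, sigma_line)
  mu <- beta_ln * (design$genotype == "ALD") +
    b[match(design$line_id, lines)]
  list(values = exp(mu + stats::rnorm(nrow(design), 0, sigma_e)),
       design = design)
}

#' Simulate an LC-MS feature table from the candidate database
#'
#' Produces one feature per (species, primary adduct) for every species of
#' the abundance table present in the database, with observed m/z drawn as
#' theoretical \eqn{\times (1 + e)}, \eqn{e \sim N(0, ppm\_sigma \cdot
#' 10^{-6})}. Internal-standard features are included with per-sample areas
#' equal to \code{is_area} (times any drift), and analyte areas are set so
#' that internal-standard normalization recovers the abundance table
#' exactly: \code{area = au / nmol * is_area}. Decoy features are placed
#' uniformly at random, at least \code{3 * tol_ppm} away from every
#' candidate of their polarity. The primary adduct of a class is the first
#' configured adduct of its preferred polarity (positive if it has any
#' positive adduct).
#'
#' @param db A \linkS4class{CandidateDB} built from \code{classes}.
#' @param study A \linkS4class{LipidomicsExperiment} (e.g. from
#'   \code{\link{simulateStudy}}) supplying abundances and the design.
#' @param classes Class definition table (for primary adducts and the
#'   class-to-standard map).
#' @param mix Standards mix table.
#' @param ppm_sigma Mass-error SD in ppm (default 2, Orbitrap-like).
#' @param decoy_rate Fraction of features that are decoys (0 <= r < 1).
#' @param tol_ppm Tolerance used to keep decoys away from candidates.
#' @param is_area Internal-standard base peak area (detector counts).
#' @param drift Optional per-sample multiplicative detector drift.
#' @param seed Integer seed.
#' @return List with \code{features} (a \linkS4class{FeatureTable}) and
#'   \code{truth} (data.frame: \code{feature_id}, \code{species},
#'   \code{adduct}, \code{is_standard}, \code{decoy}).
#' @export
simulateFeatureSpectra <- function(db, study, classes, mix,
                                   ppm_sigma = 2, decoy_rate = 0,
                                   tol_ppm = 5, is_area = 1e6,
                                   drift = NULL, seed = 1) {
  stopifnot(ppm_sigma >= 0, decoy_rate >= 0, decoy_rate < 1)
  set.seed(seed)
  e <- dbEntries(db)
  primaryAdduct <- vapply(seq_len(nrow(classes)), function(i) {
    pos <- classes$adducts_pos[[i]]
    if (length(pos)) pos[1L] else classes$adducts_neg[[i]][1L]
  }, "")
  names(primaryAdduct) <- classes$class_code
  keepPrim <- e$class_code %in% names(primaryAdduct) &
    e$adduct == primaryAdduct[e$class_code]
  prim <- e[keepPrim %in% TRUE, , drop = FALSE]

  au <- abundances(study)
  design <- designTable(study)
  ns <- ncol(au)
  if (is.null(drift)) drift <- rep(1, ns)
  stopifnot(length(drift) == ns)

  analyte <- prim[prim$species %in% rownames(au) & !prim$is_standard, ,
                  drop = FALSE]
  stds <- prim[prim$is_standard, , drop = FALSE]
  isAmt <- mix$nmol[match(classes$internal_standard[
    match(analyte$class_code, classes$class_code)], mix$species)]
  keep <- !is.na(isAmt)
  analyte <- analyte[keep, , drop = FALSE]
  isAmt <- isAmt[keep]

  n_real <- nrow(analyte) + nrow(stds)
  mzTrue <- c(analyte$mz, stds$mz)
  mzObs <- mzTrue * (1 + stats::rnorm(n_real, 0, ppm_sigma * 1e-6))
  areas <- rbind(
    au[analyte$species, , drop = FALSE] / isAmt * is_area,
    matrix(is_area, nrow(stds), ns)
  ) * rep(drift, each = n_real)
  polarity <- c(analyte$polarity, stds$polarity)
  rt <- stats::runif(n_real, 1, 15)

  n_dec <- if (decoy_rate > 0) round(decoy_rate / (1 - decoy_rate) * n_real)
  else 0L
  decMz <- numeric(0)
  decPol <- character(0)
  if (n_dec > 0) {
    pols <- unique(e$polarity)
    for (k in seq_len(n_dec)) {
      p <- sample(pols, 1L)
      rng <- range(e$mz[e$polarity == p])
      repeat {
        m <- stats::runif(1L, rng[1L], rng[2L])
        if (nrow(mzQuery(db, m, p, 3 * tol_ppm)) == 0L) break
      }
      decMz <- c(decMz, m)
      decPol <- c(decPol, p)
    }
    decAreas <- matrix(stats::rlnorm(n_dec * ns, log(is_area / 20), 1),
                       n_dec, ns)
    mzObs <- c(mzObs, decMz)
    polarity <- c(polarity, decPol)
    areas <- rbind(areas, decAreas)
    rt <- c(rt, stats::runif(n_dec, 1, 15))
  }

  ids <- sprintf("F%05d", seq_along(mzObs))
  info <- data.frame(feature_id = ids, mz = mzObs, polarity = polarity,
                     rt = rt, stringsAsFactors = FALSE)
  colnames(areas) <- design$sample_id
  truth <- data.frame(
    feature_id = ids,
    species = c(analyte$species, stds$species, rep(NA_character_, n_dec)),
    adduct = c(analyte$adduct, stds$adduct, rep(NA_character_, n_dec)),
    is_standard = c(rep(FALSE, nrow(analyte)), rep(TRUE, nrow(stds)),
                    rep(FALSE, n_dec)),
    decoy = c(rep(FALSE, n_real), rep(TRUE, n_dec)),
    stringsAsFactors = FALSE
  )
  list(features = FeatureTable(info, areas), truth = truth)
}
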