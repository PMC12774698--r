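## Lipid-class definitions, sum-composition expansion and adduct m/z.
##
## A lipid class is defined by a generic formula in which the radyl
## substituents are abstracted away: base_formula is the composition at the
## formal reference point of zero radyl carbons and zero radyl double bonds,
## so a species at sum composition (C:db) has
##   neutral_formula = base_formula + C * CH2 - db * H2.
## Base formulas are anchored to a species of independently known
## composition (the class's internal standard where one exists) and shipped
## as an editable TSV, not hard-coded.

.CH2 <- c(C = 1L, H = 2L)
.H2 <- c(H = 2L)

#' Read a lipid-class definition table
#'
#' Reads the TSV format with columns \code{class_code}, \code{base_formula},
#' \code{n_chains}, \code{c_min}, \code{c_max}, \code{db_min}, \code{db_max},
#' \code{adducts_pos}, \code{adducts_neg} (comma-separated adduct names),
#' \code{internal_standard}, and the anchor columns \code{anchor_c},
#' \code{anchor_db}, \code{anchor_formula} documenting the reference species
#' each base formula was derived from.
#'
#' @param path File path; defaults to the shipped class set covering the
#'   classes of a brain-organoid lipidome (CE, PC, TG, sphingolipids,
#'   gangliosides, sulfatides, lysophospholipids, ...).
#' @return A data.frame with one row per class; \code{adducts_pos} and
#'   \code{adducts_neg} are list columns of adduct-name character vectors.
#' @export
readClassDefinitions <- function(path = system.file("extdata",
                                                    "lipid_classes.tsv",
                                                    package = "lipidsum")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  required <- c("class_code", "base_formula", "n_chains", "c_min", "c_max",
                "db_min", "db_max", "adducts_pos", "adducts_neg",
                "internal_standard")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("class definition file lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$class_code)) {
    stop("duplicate class_code in class definitions: ",
         paste(unique(df$class_code[duplicated(df$class_code)]),
               collapse = ", "))
  }
  splitAdducts <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || !nzchar(s)) character(0)
      else trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    })
  }
  df$adducts_pos <- splitAdducts(df$adducts_pos)
  df$adducts_neg <- splitAdducts(df$adducts_neg)
  for (i in seq_len(nrow(df))) {
    if (df$c_min[i] < 0 || df$db_min[i] < 0) {
      stop("negative enumeration range for class ", df$class_code[i])
    }
    if (df$n_chains[i] < 1L) {
      stop("n_chains must be >= 1 for class ", df$class_code[i])
    }
    if (!length(df$adducts_pos[[i]]) && !length(df$adducts_neg[[i]])) {
      stop("class ", df$class_code[i], " has no adducts in either polarity")
    }
    parseFormula(df$base_formula[i])  # validates
  }
  df
}

#' Read an adduct specification table
#'
#' Columns: \code{name} (e.g. \code{"[M+H]+"}), \code{delta_formula}
#' (composition added to or removed from the molecule), \code{sign}
#' (+1 addition / -1 loss), \code{z} (signed charge), \code{n_M} (number of
#' neutral molecules in the ion).
#'
#' @param path File path; defaults to the shipped electrospray adduct set.
#' @return data.frame, one row per adduct.
#' @export
readAdductTable <- function(path = system.file("extdata", "adducts.tsv",
                                               package = "lipidsum")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  required <- c("name", "delta_formula", "sign", "z", "n_M")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("adduct file lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$z == 0)) stop("adduct charge z must be nonzero")
  if (any(df$n_M < 1)) stop("adduct n_M must be >= 1")
  pol_name <- ifelse(grepl("\\]\\s*[0-9]*\\+$", df$name), 1L,
                     ifelse(grepl("\\]\\s*[0-9]*-$", df$name), -1L, NA))
  if (any(!is.na(pol_name) & sign(df$z) != pol_name)) {
    stop("adduct name polarity does not match sign of z for: ",
         paste(df$name[!is.na(pol_name) & sign(df$z) != pol_name],
               collapse = ", "))
  }
  df$polarity <- ifelse(df$z > 0, "+", "-")
  df
}

#' Read an internal-standards mix table
#'
#' Columns: \code{species} (standard name, e.g. \code{"CE(16:0)-d7"}),
#' \code{class_code} (class the standard quantifies, also deciding its
#' adducts), \code{formula} (explicit composition, supporting deuterium),
#' \code{nmol} (amount spiked per sample), and \code{ref_mass} (independently
#' computed monoisotopic mass kept as a cross-check fixture).
#'
#' @param path File path; defaults to the shipped mix.
#' @return data.frame, one row per standard.
#' @export
readStandardsMix <- function(path = system.file("extdata",
                                                "standards_mix.tsv",
                                                package = "lipidsum")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  required <- c("species", "class_code", "formula", "nmol")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("standards mix file lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(df$nmol <= 0)) stop("standard amounts must be > 0")
  if (anyDuplicated(df$species)) stop("duplicate species in standards mix")
  df
}

#' Canonical sum-composition species name
#'
#' @param class_code Class code, e.g. \code{"PC"}.
#' @param c_total Total radyl carbons.
#' @param db_total Total radyl double bonds.
#' @return \code{"CLASS(C:db)"}, e.g. \code{"PC(54:3)"}.
#' @export
speciesName <- function(class_code, c_total, db_total) {
  sprintf("%s(%d:%d)", class_code, as.integer(c_total), as.integer(db_total))
}

#' Parse a canonical species name
#'
#' Inverse of \code{\link{speciesName}}: \code{parseSpeciesName("PC(54:3)")}
#' gives class \code{"PC"}, 54 carbons, 3 double bonds.
#'
#' @param name Character vector of \code{"CLASS(C:db)"} names.
#' @return data.frame with columns \code{class_code}, \code{c_total},
#'   \code{db_total}; rows of unparseable names are \code{NA}.
#' @export
parseSpeciesName <- function(name) {
  m <- regmatches(name, regexec("^(.*)\\((\\d+):(\\d+)\\)$", name))
  out <- data.frame(
    class_code = vapply(m, function(x) if (length(x) == 4L) x[2] else NA_character_, ""),
    c_total = vapply(m, function(x) if (length(x) == 4L) as.integer(x[3]) else NA_integer_, 0L),
    db_total = vapply(m, function(x) if (length(x) == 4L) as.integer(x[4]) else NA_integer_, 0L),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Maximum double bonds allowed at a given chain carbon total
#'
#' Default unsaturation constraint used during expansion: at most
#' \code{floor(C / 2)} total double bonds. Supply a different function (or
#' \code{NULL} for no constraint) to \code{\link{expandClass}}.
#'
#' @param c_total Total radyl carbons.
#' @param n_chains Number of radyl chains of the class (unused by the
#'   default rule but part of the constraint signature).
#' @return Integer maximum double-bond count.
#' @export
defaultDbConstraint <- function(c_total, n_chains) floor(c_total / 2)

#' Expand a lipid class into sum-composition species
#'
#' Replaces the abstract radyl content of the class's generic formula with
#' every total carbon count in \code{[c_min, c_max]} and double-bond count in
#' \code{[db_min, db_max]} subject to the unsaturation constraint, producing
#' one candidate species per (C, db) pair with its neutral formula and
#' monoisotopic mass. Odd carbon totals are enumerated (odd-chain species
#' such as CE(35:1) occur in real data).
#'
#' @param defn One row of a class definition table
#'   (\code{\link{readClassDefinitions}}).
#' @param constraint \code{NULL} for none, or a function
#'   \code{(c_total, n_chains) -> max db}; default
#'   \code{\link{defaultDbConstraint}}.
#' @return data.frame sorted by (C, db) with columns \code{species},
#'   \code{class_code}, \code{c_total}, \code{db_total}, \code{n_chains},
#'   \code{formula}, \code{neutral_mass}. Zero rows if the ranges or the
#'   constraint admit no pair.
#' @export
#' @examples
#' classes <- readClassDefinitions()
#' pc <- expandClass(classes[classes$class_code == "PC", ])
#' head(pc)
expandClass <- function(defn, constraint = defaultDbConstraint) {
  stopifnot(nrow(defn) == 1L)
  base <- parseFormula(defn$base_formula)
  cs <- seq.int(defn$c_min, length.out = max(0L, defn$c_max - defn$c_min + 1L))
  dbs <- seq.int(defn$db_min, length.out = max(0L, defn$db_max - defn$db_min + 1L))
  if (!length(cs) || !length(dbs)) {
    return(data.frame(species = character(0), class_code = character(0),
                      c_total = integer(0), db_total = integer(0),
                      n_chains = integer(0), formula = character(0),
                      neutral_mass = numeric(0), stringsAsFactors = FALSE))
  }
  grid <- expand.grid(db_total = dbs, c_total = cs,
                      KEEP.OUT.ATTRS = FALSE)[, c("c_total", "db_total")]
  if (!is.null(constraint)) {
    keep <- grid$db_total <= constraint(grid$c_total, defn$n_chains)
    grid <- grid[keep, , drop = FALSE]
  }
  grid <- grid[order(grid$c_total, grid$db_total), , drop = FALSE]
  n <- nrow(grid)
  formulas <- character(n)
  masses <- numeric(n)
  base_mass <- monoisotopicMass(base)
  ch2_mass <- monoisotopicMass(.CH2)
  h2_mass <- monoisotopicMass(.H2)
  for (i in seq_len(n)) {
    f <- subtractFormulas(
      addFormulas(base, multiplyFormula(.CH2, grid$c_total[i])),
      multiplyFormula(.H2, grid$db_total[i])
    )
    formulas[i] <- formulaToString(f)
    masses[i] <- monoisotopicMass(f)
  }
  data.frame(
    species = speciesName(defn$class_code, grid$c_total, grid$db_total),
    class_code = defn$class_code,
    c_total = grid$c_total,
    db_total = grid$db_total,
    n_chains = defn$n_chains,
    formula = formulas,
    neutral_mass = masses,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Adduct m/z from a neutral monoisotopic mass
#'
#' Computes \eqn{m/z = (n_M M \pm m(\Delta) - z m_e) / |z|}: the mass of
#' \code{n_M} neutral molecules plus or minus the adduct's delta composition,
#' corrected for the electron mass times the signed charge, divided by the
#' absolute charge. Strictly increasing in \code{neutral_mass} for a fixed
#' adduct.
#'
#' @param neutral_mass Neutral monoisotopic mass (Da), > 0. Vectorized.
#' @param adduct One row of an adduct table (\code{\link{readAdductTable}}).
#' @param table Isotope mass table.
#' @return m/z in Th.
#' @export
#' @examples
#' ad <- readAdductTable()
#' adductMz(18.010565, ad[ad$name == "[M+H]+", ])  # water + proton
adductMz <- function(neutral_mass, adduct, table = isotopeMasses()) {
  stopifnot(nrow(adduct) == 1L)
  if (any(neutral_mass <= 0)) stop("neutral_mass must be > 0")
  if (adduct$z == 0) stop("adduct charge z must be nonzero")
  delta <- if (nzchar(adduct$delta_formula)) {
    monoisotopicMass(parseFormula(adduct$delta_formula), table)
  } else 0
  (adduct$n_M * neutral_mass + adduct$sign * delta -
     adduct$z * electronMass()) / abs(adduct$z)
}
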