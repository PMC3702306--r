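# Residue mass tables and mass/charge arithmetic.

# Monoisotopic residue masses (Da), standard 20 amino acids.
.MONO_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Average residue masses (Da).
.AVG_RESIDUE <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.H_MONO <- 1.0078250319
.H_AVG <- 1.00794

#' Build a residue mass table
#'
#' Returns the residue and constant masses used throughout the package under
#' one of three conventions:
#'
#' * `"monoisotopic"` — lightest-isotope masses; the default for theoretical
#'   fragment ladders and precursor m/z.
#' * `"average"` — abundance-weighted mean masses.
#' * `"nominal"` — average residue masses rounded to 2 decimals with a
#'   phosphate delta of exactly 80.00 Da; the convention used when spectra
#'   are annotated by hand (e.g. S = 87.08, P = 97.12, T = 101.11).
#'
#' The z-dot constant is the mass added to a C-terminal residue sum to give
#' the neutral z-radical (z+1) fragment, derived as water + H - NH3 so that
#' complementary c and z-dot fragments sum to the peptide mass plus one
#' hydrogen atom.
#'
#' @param kind one of `"monoisotopic"`, `"average"`, `"nominal"`.
#' @param overrides optional named numeric vector (or path to a `key=value`
#'   text file, see [read_mass_config()]) overriding individual entries;
#'   names are single residue letters or one of `water`, `ammonia`, `proton`,
#'   `z_dot`, `phospho`.
#' @return An object of class `mass_table`: a list with elements `kind`,
#'   `residue` (named vector of 20 residue masses, Da), `water`, `ammonia`,
#'   `proton`, `z_dot` and `phospho` (all Da).
#' @examples
#' tab <- mass_table("nominal")
#' tab$residue[c("S", "P", "T")]  # 87.08, 97.12, 101.11
#' @export
mass_table <- function(kind = c("monoisotopic", "average", "nominal"),
                       overrides = NULL) {
  kind <- match.arg(kind)
  tab <- switch(kind,
    monoisotopic = list(
      kind = kind, residue = .MONO_RESIDUE,
      water = 18.010565, ammonia = 17.026549, proton = 1.00728,
      z_dot = 18.010565 + .H_MONO - 17.026549,  # 1.991841
      phospho = 79.96633
    ),
    average = list(
      kind = kind, residue = .AVG_RESIDUE,
      water = 18.01528, ammonia = 17.03052, proton = 1.00728,
      z_dot = 18.01528 + .H_AVG - 17.03052,  # 1.99270
      phospho = 79.9799
    ),
    nominal = list(
      kind = kind, residue = round(.AVG_RESIDUE, 2),
      water = 18.02, ammonia = 17.03, proton = 1.00728,
      z_dot = round(18.01528 + .H_AVG - 17.03052, 2),
      phospho = 80.00
    )
  )
  if (!is.null(overrides)) {
    if (is.character(overrides) && length(overrides) == 1L)
      overrides <- read_mass_config(overrides)
    stopifnot(is.numeric(overrides), !is.null(names(overrides)))
    for (nm in names(overrides)) {
      if (nm %in% names(tab$residue)) tab$residue[[nm]] <- overrides[[nm]]
      else if (nm %in% c("water", "ammonia", "proton", "z_dot", "phospho"))
        tab[[nm]] <- overrides[[nm]]
      else stop("unknown mass table key: ", nm)
    }
  }
  if (any(tab$residue <= 0) || length(tab$residue) != 20L)
    stop("mass table must contain 20 positive residue masses")
  class(tab) <- "mass_table"
  tab
}

#' Read mass-table overrides from a key=value file
#'
#' One `key=value` pair per line; keys are residue letters or the constant
#' names accepted by [mass_table()]. Blank lines and lines starting with `#`
#' are ignored.
#'
#' @param path path to a plain-text config file.
#' @return named numeric vector of overrides.
#' @export
read_mass_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad))
    stop("malformed key=value line in ", path, ": ", lines[which(bad)[1]])
  vals <- suppressWarnings(as.numeric(trimws(vapply(parts, `[`, "", 2L))))
  if (anyNA(vals))
    stop("non-numeric value in ", path)
  stats::setNames(vals, trimws(vapply(parts, `[`, "", 1L)))
}

#' @export
print.mass_table <- function(x, ...) {
  cat(sprintf("<mass_table: %s>  water=%.5f ammonia=%.5f proton=%.5f z_dot=%.5f phospho=%.5f\n",
              x$kind, x$water, x$ammonia, x$proton, x$z_dot, x$phospho))
  invisible(x)
}

#' Define a residue modification
#'
#' @param name modification name, e.g. `"phospho"`.
#' @param delta mass shift in Da (non-zero).
#' @param position 1-based position within the peptide.
#' @param allowed_residues residue letters the modification may sit on.
#' @return list of class `modification`.
#' @export
modification <- function(name, delta, position,
                         allowed_residues = c("S", "T", "Y")) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(delta), length(delta) == 1L, delta != 0,
            is.numeric(position), length(position) == 1L, position >= 1)
  structure(list(name = name, delta = as.numeric(delta),
                 position = as.integer(position),
                 allowed_residues = allowed_residues),
            class = "modification")
}

#' Phosphorylation modification at a peptide position
#'
#' @param position 1-based position within the peptide (must be S, T or Y).
#' @param tab mass table supplying the phosphate delta (HPO3; nominally
#'   "+80 Da", 79.96633 monoisotopic).
#' @return a [modification()].
#' @export
phospho <- function(position, tab = mass_table("monoisotopic")) {
  modification("phospho", tab$phospho, position)
}

#' Construct a peptide
#'
#' A peptide is a sequence plus its coordinate in the parent protein and an
#' optional list of modifications. `protein_start` is the 1-based protein
#' coordinate of the first peptide residue, so peptide position `i` maps to
#' protein residue `protein_start + i - 1`.
#'
#' @param sequence uppercase amino-acid string (standard 20-letter alphabet).
#' @param protein_id identifier of the parent protein.
#' @param protein_start 1-based protein coordinate of the first residue.
#' @param modifications list of [modification()] objects.
#' @return list of class `peptide`.
#' @examples
#' p <- peptide("SSSSGDQSSDSLNSPTLLAL", protein_start = 307,
#'              modifications = list(phospho(14)))
#' @export
peptide <- function(sequence, protein_id = "", protein_start = 1L,
                    modifications = list()) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence), protein_start >= 1)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(res %in% names(.MONO_RESIDUE)))
    stop("sequence contains non-standard residues: ",
         paste(unique(res[!res %in% names(.MONO_RESIDUE)]), collapse = ","))
  if (inherits(modifications, "modification"))
    modifications <- list(modifications)
  pos <- vapply(modifications, function(m) m$position, 1L)
  if (anyDuplicated(pos)) stop("duplicate modification positions")
  if (length(pos) && any(pos > length(res)))
    stop("modification position beyond peptide length")
  for (m in modifications)
    if (!res[m$position] %in% m$allowed_residues)
      stop(sprintf("residue %s at position %d not allowed for %s",
                   res[m$position], m$position, m$name))
  structure(list(sequence = sequence, protein_id = protein_id,
                 protein_start = as.integer(protein_start),
                 modifications = modifications),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  mods <- if (length(x$modifications))
    paste(vapply(x$modifications,
                 function(m) sprintf("%s@%d", m$name, m$position), ""),
          collapse = ",") else "none"
  cat(sprintf("<peptide %s [%s %d-%d] mods: %s>\n", x$sequence,
              if (nzchar(x$protein_id)) x$protein_id else "?",
              x$protein_start, x$protein_start + nchar(x$sequence) - 1L, mods))
  invisible(x)
}

# Per-position modification deltas for a peptide (numeric vector, length n).
mod_deltas <- function(p) {
  d <- numeric(nchar(p$sequence))
  for (m in p$modifications) d[m$position] <- d[m$position] + m$delta
  d
}

#' Neutral monoisotopic/average mass of a peptide
#'
#' Sum of residue masses plus one water plus all modification deltas.
#'
#' @param p a [peptide()].
#' @param tab a [mass_table()].
#' @return neutral mass in Da.
#' @export
peptide_neutral_mass <- function(p, tab = mass_table("monoisotopic")) {
  stopifnot(inherits(p, "peptide"), inherits(tab, "mass_table"))
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  sum(tab$residue[res]) + tab$water + sum(mod_deltas(p))
}

#' m/z of a neutral mass at a given charge
#'
#' `(neutral + z * proton) / z` with the table's proton mass.
#'
#' @param neutral neutral mass in Da.
#' @param z positive integer charge.
#' @param tab a [mass_table()].
#' @return m/z.
#' @export
mz <- function(neutral, z, tab = mass_table("monoisotopic")) {
  if (any(z < 1) || any(z != as.integer(z)))
    stop("charge must be a positive integer")
  (neutral + z * tab$proton) / z
}
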