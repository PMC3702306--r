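# In-silico tryptic digestion and phosphoform enumeration.

#' Digestion parameters
#'
#' @param enzyme only `"trypsin"` is supported: cleave C-terminal to K or R
#'   except when the next residue is proline.
#' @param max_missed_cleavages maximum internal uncleaved K/R sites (0-5).
#' @param min_length,max_length peptide length filter.
#' @return list of class `digest_params`.
#' @export
digest_params <- function(enzyme = "trypsin", max_missed_cleavages = 2L,
                          min_length = 5L, max_length = 50L) {
  enzyme <- match.arg(enzyme, "trypsin")
  stopifnot(max_missed_cleavages >= 0, max_missed_cleavages <= 5,
            min_length >= 1, min_length <= max_length)
  structure(list(enzyme = enzyme,
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "digest_params")
}

# Tryptic cleavage points: positions i such that the bond after residue i is
# cut (residue i is K/R and residue i+1 is not P). Returns integer vector.
tryptic_sites <- function(residues) {
  n <- length(residues)
  if (n < 2L) return(integer(0))
  i <- which(residues[-n] %in% c("K", "R"))
  i[residues[i + 1L] != "P"]
}

#' Digest a protein in silico
#'
#' Applies the trypsin rule (cleave after K/R unless followed by P) and
#' enumerates all fully tryptic peptides with up to
#' `params$max_missed_cleavages` internal missed cleavage sites, subject to
#' the length filter. Peptides are ordered by protein start, then length.
#'
#' @param sequence protein amino-acid string (uppercase standard alphabet).
#' @param params a [digest_params()].
#' @param protein_id identifier propagated to the peptides.
#' @return list of [peptide()] objects.
#' @examples
#' digest("AKRP", digest_params(max_missed_cleavages = 0, min_length = 1))
#' @export
digest <- function(sequence, params = digest_params(), protein_id = "") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty protein sequence")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  # segment boundaries: 0, cleavage points, n
  cuts <- c(0L, tryptic_sites(res), n)
  nseg <- length(cuts) - 1L
  out <- list()
  for (a in seq_len(nseg)) {
    for (b in a:min(nseg, a + params$max_missed_cleavages)) {
      from <- cuts[a] + 1L
      to <- cuts[b + 1L]
      len <- to - from + 1L
      if (len < params$min_length || len > params$max_length) next
      out[[length(out) + 1L]] <- peptide(
        paste(res[from:to], collapse = ""),
        protein_id = protein_id, protein_start = from)
    }
  }
  ord <- order(vapply(out, function(p) p$protein_start, 1L),
               vapply(out, function(p) nchar(p$sequence), 1L))
  out[ord]
}

#' Enumerate phosphoforms of a peptide
#'
#' All placements of `n_phospho` phosphate groups on the peptide's S/T/Y
#' residues, in ascending position-tuple order. With `n_phospho = 0` the
#' unmodified peptide is returned; when the peptide has fewer than
#' `n_phospho` acceptor residues the list is empty.
#'
#' @param p a [peptide()] (any existing modifications are kept).
#' @param n_phospho number of phosphates to place.
#' @param tab mass table supplying the phosphate delta.
#' @return list of [peptide()] objects.
#' @export
enumerate_phosphoforms <- function(p, n_phospho = 1L,
                                   tab = mass_table("monoisotopic")) {
  stopifnot(inherits(p, "peptide"), n_phospho >= 0)
  if (n_phospho == 0L) return(list(p))
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  sty <- which(res %in% c("S", "T", "Y"))
  sty <- setdiff(sty, vapply(p$modifications, function(m) m$position, 1L))
  if (length(sty) < n_phospho) return(list())
  # index into sty to avoid combn's scalar-as-sequence behaviour
  combos <- lapply(utils::combn(seq_along(sty), n_phospho,
                                simplify = FALSE), function(i) sty[i])
  lapply(combos, function(pos) {
    mods <- c(p$modifications, lapply(pos, phospho, tab = tab))
    peptide(p$sequence, p$protein_id, p$protein_start, mods)
  })
}

#' Find candidate peptides for a precursor
#'
#' Digests the protein, enumerates phosphoforms carrying `0..n_phospho`
#' phosphates, and returns all forms whose theoretical precursor m/z at
#' charge `z` lies within `tol` Da of the observed value, sorted by absolute
#' m/z error.
#'
#' @param sequence protein sequence.
#' @param precursor_mz observed precursor m/z.
#' @param z precursor charge.
#' @param tol precursor tolerance in Da (the search default is 2.5).
#' @param params a [digest_params()].
#' @param n_phospho maximum number of phosphates to consider.
#' @param tab a [mass_table()].
#' @param protein_id identifier propagated to the peptides.
#' @return list of [peptide()] objects sorted by `abs(mz error)`, with the
#'   error in attribute `"mz_error"` on each element.
#' @export
find_peptide <- function(sequence, precursor_mz, z, tol = 2.5,
                         params = digest_params(), n_phospho = 1L,
                         tab = mass_table("monoisotopic"), protein_id = "") {
  stopifnot(tol > 0, z >= 1)
  base <- digest(sequence, params, protein_id)
  hits <- list()
  errs <- numeric(0)
  for (bp in base) {
    for (k in 0:n_phospho) {
      for (form in enumerate_phosphoforms(bp, k, tab)) {
        err <- mz(peptide_neutral_mass(form, tab), z, tab) - precursor_mz
        if (abs(err) <= tol) {
          hits[[length(hits) + 1L]] <- structure(form, mz_error = err)
          errs <- c(errs, err)
        }
      }
    }
  }
  hits[order(abs(errs))]
}

#' Write a peptide list as TSV
#'
#' Columns: protein_id, start, end, sequence, mods (`name@position`,
#' comma-separated), neutral_mass.
#'
#' @param peptides list of [peptide()] objects.
#' @param path output file.
#' @param tab mass table for the neutral-mass column.
#' @return the path, invisibly.
#' @export
write_peptides_tsv <- function(peptides, path,
                               tab = mass_table("monoisotopic")) {
  df <- peptides_df(peptides, tab)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

peptides_df <- function(peptides, tab = mass_table("monoisotopic")) {
  data.frame(
    protein_id = vapply(peptides, function(p) p$protein_id, ""),
    start = vapply(peptides, function(p) p$protein_start, 1L),
    end = vapply(peptides,
                 function(p) p$protein_start + nchar(p$sequence) - 1L, 1L),
    sequence = vapply(peptides, function(p) p$sequence, ""),
    mods = vapply(peptides, function(p) {
      if (!length(p$modifications)) return("")
      paste(vapply(p$modifications,
                   function(m) sprintf("%s@%d", m$name, m$position), ""),
            collapse = ",")
    }, ""),
    neutral_mass = vapply(peptides, peptide_neutral_mass, 1.0, tab = tab),
    stringsAsFactors = FALSE
  )
}
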