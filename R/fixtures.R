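# Packaged Fra-2 example data.

#' Packaged Fra-2 phosphopeptide example
#'
#' Paths and objects for the worked Fra-2 S320/T322 example: a synthetic
#' protein context whose residues 307-326 are the authentic tryptic
#' phosphopeptide `SSSSGDQSSDSLNSPTLLAL` (peptide position 14 = S320,
#' position 16 = T322), and two ETD peak lists. In each MGF the two bracket
#' ions that carry the localization arithmetic are reported observations
#' (upper reading: c13 1269.7 / c15 1534.8; lower reading: c13 1269.6 /
#' c16 1634.7); the remaining series peaks are synthetic reconstructions at
#' theoretical positions, as described in the files themselves.
#'
#' The published residue numbering of this peptide is internally inconsistent
#' (a 20-residue sequence labelled with a 10-coordinate span); the fixture
#' adopts the mapping that places the named sites S320/T322 at peptide
#' positions 14/16 and does not renumber anything else.
#'
#' @return list with elements `fasta`, `mgf_s320`, `mgf_t322` (file paths)
#'   and `peptide` (the unmodified [peptide()] with `protein_start = 307`).
#' @examples
#' fx <- fra2_example()
#' basename(fx$fasta)
#' @export
fra2_example <- function() {
  ext <- function(f) system.file("extdata", f, package = "phosloc",
                                 mustWork = TRUE)
  list(fasta = ext("fra2_region_synthetic.fasta"),
       mgf_s320 = ext("fra2_s320_etd_synthetic.mgf"),
       mgf_t322 = ext("fra2_t322_etd_synthetic.mgf"),
       peptide = peptide("SSSSGDQSSDSLNSPTLLAL", protein_id = "FRA2_SYN",
                         protein_start = 307L))
}
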