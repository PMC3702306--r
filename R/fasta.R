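# Protein FASTA input (Biostrings-backed).

#' Read proteins from a FASTA file
#'
#' Multi-record, wrapped-line FASTA. The first whitespace-delimited token of
#' each header is the protein id; the remainder is the description.
#'
#' @param path FASTA file.
#' @return data.frame with columns `id`, `sequence`, `description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop("no records in FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs)
  if (any(!nzchar(seqs)))
    stop("empty sequence in FASTA file: ", path)
  if (!all(ok))
    stop("non-standard residues in FASTA record(s): ",
         paste(ids[!ok], collapse = ", "))
  data.frame(id = ids, sequence = unname(seqs), description = unname(desc),
             stringsAsFactors = FALSE)
}
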