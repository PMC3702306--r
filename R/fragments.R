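# Theoretical fragment ladders for ETD (c / z-dot) and CID (b / y).
#
# ETD cleaves the backbone N-Calpha bond: N-terminal fragments are c ions
# (prefix + NH3), C-terminal fragments are z-dot radicals (suffix + z_dot
# constant), and the bond N-terminal to a proline does not break, so the c/z
# ions at pre-proline bonds are flagged `suppressed` rather than omitted.

ladder_df <- function(series, index, charge, neutral, mzv, suppressed) {
  data.frame(series = series, index = as.integer(index),
             charge = as.integer(charge), mz = mzv, neutral = neutral,
             suppressed = suppressed, stringsAsFactors = FALSE)
}

#' Theoretical c-ion ladder
#'
#' Ions c1..c(n-1): neutral mass of c_i is the sum of residues 1..i (plus any
#' modifications at positions <= i) plus NH3. `suppressed` is TRUE when
#' residue i+1 is proline (the bond does not cleave in ETD).
#'
#' @param p a [peptide()] of length >= 2.
#' @param tab a [mass_table()].
#' @param charge positive integer fragment charge.
#' @return data.frame with columns `series`, `index`, `charge`, `mz`,
#'   `neutral`, `suppressed`.
#' @export
c_ladder <- function(p, tab = mass_table("monoisotopic"), charge = 1L) {
  frag_prefix(p, tab, charge, series = "c", constant = tab$ammonia)
}

#' Theoretical z-dot ladder
#'
#' Ions z1..z(n-1) as z+1 radical species, the dominant ETD C-terminal
#' product: neutral mass of z_j is the sum of the last j residues (plus their
#' modifications) plus the z-dot constant. `suppressed` is TRUE when residue
#' n-j+1 is proline (the complementary pre-proline bond).
#'
#' @inheritParams c_ladder
#' @return data.frame as in [c_ladder()], `series = "z"`.
#' @export
z_ladder <- function(p, tab = mass_table("monoisotopic"), charge = 1L) {
  frag_suffix(p, tab, charge, series = "z", constant = tab$z_dot)
}

#' Theoretical b-ion ladder (CID)
#'
#' @inheritParams c_ladder
#' @return data.frame as in [c_ladder()]; b ions are never suppressed.
#' @export
b_ladder <- function(p, tab = mass_table("monoisotopic"), charge = 1L) {
  frag_prefix(p, tab, charge, series = "b", constant = 0)
}

#' Theoretical y-ion ladder (CID)
#'
#' @inheritParams c_ladder
#' @return data.frame as in [c_ladder()]; y ions are never suppressed.
#' @export
y_ladder <- function(p, tab = mass_table("monoisotopic"), charge = 1L) {
  frag_suffix(p, tab, charge, series = "y", constant = tab$water)
}

frag_prefix <- function(p, tab, charge, series, constant) {
  check_frag_args(p, charge)
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  cum <- cumsum(tab$residue[res] + mod_deltas(p))
  idx <- seq_len(n - 1L)
  neutral <- unname(cum[idx]) + constant
  supp <- if (series == "c") res[idx + 1L] == "P" else rep(FALSE, n - 1L)
  ladder_df(series, idx, charge, neutral, mz(neutral, charge, tab), supp)
}

frag_suffix <- function(p, tab, charge, series, constant) {
  check_frag_args(p, charge)
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  cum <- cumsum(rev(tab$residue[res] + mod_deltas(p)))  # cum[j] = last j
  idx <- seq_len(n - 1L)
  neutral <- unname(cum[idx]) + constant
  supp <- if (series == "z") res[n - idx + 1L] == "P" else rep(FALSE, n - 1L)
  ladder_df(series, idx, charge, neutral, mz(neutral, charge, tab), supp)
}

check_frag_args <- function(p, charge) {
  stopifnot(inherits(p, "peptide"))
  if (nchar(p$sequence) < 2L) stop("peptide must have at least 2 residues")
  if (length(charge) != 1L || charge < 1 || charge != as.integer(charge))
    stop("invalid fragment charge")
}

#' Combined fragment ladders across series and charges
#'
#' @param p a [peptide()].
#' @param tab a [mass_table()].
#' @param charges vector of positive integer charges.
#' @param series subset of `c("c", "z", "b", "y")` (`"z"` means z-dot).
#' @return one data.frame, sorted by series, index, charge.
#' @export
ladder_set <- function(p, tab = mass_table("monoisotopic"), charges = 1L,
                       series = c("c", "z")) {
  if (!length(series)) stop("at least one fragment series is required")
  series <- match.arg(series, c("c", "z", "b", "y"), several.ok = TRUE)
  if (!length(charges)) stop("at least one fragment charge is required")
  gen <- list(c = c_ladder, z = z_ladder, b = b_ladder, y = y_ladder)
  out <- do.call(rbind, unlist(lapply(series, function(s)
    lapply(charges, function(z) gen[[s]](p, tab, z))), recursive = FALSE))
  out <- out[order(out$series, out$index, out$charge), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a fragment ladder as TSV
#'
#' @param ladder data.frame from [ladder_set()] or the `*_ladder()` functions.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_ladder_tsv <- function(ladder, path) {
  utils::write.table(ladder, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
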