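# Tolerance-based assignment of theoretical fragment ions to observed peaks.

#' Match a theoretical ladder against an observed peak list
#'
#' Each non-suppressed theoretical ion is paired with the nearest observed
#' peak within `product_tol` Da. Assignment is deterministic: within a series
#' ions are processed in ascending index (then charge) order and each peak
#' may be used once per series (a peak may still serve ions of a different
#' series); among equidistant peaks the lower m/z wins.
#'
#' @param s a [spectrum()].
#' @param ladders data.frame of theoretical ions from [ladder_set()] or the
#'   `*_ladder()` functions.
#' @param product_tol product (fragment) mass tolerance in Da; the search
#'   default is 0.7.
#' @param peptide optional [peptide()] the ladder was computed from; carried
#'   along for gap/localization steps.
#' @param tab the [mass_table()] the ladder was computed with; carried along.
#' @return object of class `match_result`: list with `assignments`
#'   (data.frame: series, index, charge, theo_mz, peak_mz, intensity, error),
#'   `unmatched` (theoretical ions without a peak, with their `suppressed`
#'   flag), `spectrum_id`, `product_tol`, `peptide`, `tab`.
#' @export
match_spectrum <- function(s, ladders, product_tol = 0.7, peptide = NULL,
                           tab = mass_table("monoisotopic")) {
  stopifnot(inherits(s, "spectrum"), product_tol > 0)
  if (!nrow(ladders)) stop("empty fragment ladder")
  pk <- s$peaks
  asg <- list()
  una <- list()
  for (ser in unique(ladders$series)) {
    sub <- ladders[ladders$series == ser, , drop = FALSE]
    sub <- sub[order(sub$index, sub$charge), , drop = FALSE]
    used <- rep(FALSE, nrow(pk))
    for (r in seq_len(nrow(sub))) {
      ion <- sub[r, ]
      if (ion$suppressed) {
        una[[length(una) + 1L]] <- ion
        next
      }
      hit <- NA_integer_
      if (nrow(pk)) {
        d <- abs(pk$mz - ion$mz)
        d[used] <- Inf
        ok <- which(d <= product_tol)
        if (length(ok)) {
          best <- ok[d[ok] == min(d[ok])]
          hit <- best[which.min(pk$mz[best])]  # tie -> lower peak m/z
        }
      }
      if (is.na(hit)) {
        una[[length(una) + 1L]] <- ion
      } else {
        used[hit] <- TRUE
        asg[[length(asg) + 1L]] <- data.frame(
          series = ion$series, index = ion$index, charge = ion$charge,
          theo_mz = ion$mz, peak_mz = pk$mz[hit],
          intensity = pk$intensity[hit], error = pk$mz[hit] - ion$mz,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_asg <- data.frame(series = character(0), index = integer(0),
                          charge = integer(0), theo_mz = numeric(0),
                          peak_mz = numeric(0), intensity = numeric(0),
                          error = numeric(0))
  structure(list(
    assignments = if (length(asg)) do.call(rbind, asg) else empty_asg,
    unmatched = if (length(una)) do.call(rbind, una) else
      ladders[0, , drop = FALSE],
    spectrum_id = s$id, product_tol = product_tol,
    peptide = peptide, tab = tab), class = "match_result")
}

#' Matched indices of one series
#'
#' @param m a `match_result`.
#' @param series series letter.
#' @param charge fragment charge to restrict to.
#' @return sorted integer vector of matched ladder indices.
#' @export
matched_indices <- function(m, series = "c", charge = 1L) {
  a <- m$assignments
  sort(unique(a$index[a$series == series & a$charge == charge]))
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result '%s': %d matched / %d unmatched ions, tol %.2f Da>\n",
              x$spectrum_id, nrow(x$assignments), nrow(x$unmatched),
              x$product_tol))
  invisible(x)
}
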