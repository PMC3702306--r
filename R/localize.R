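# Bracket-gap phosphate localization and identity verification.
#
# The localization logic works on observed peak differences: two matched
# ladder ions bracketing unobserved cleavage positions define a gap whose
# observed mass must equal the spanned residues' summed mass, plus ~80 Da per
# phosphate if a phosphate sits in the span. The S/T/Y residues inside such a
# span are the candidate sites ("site-determining ions").

#' Bracket gaps between consecutive matched ladder ions
#'
#' For every consecutive pair of matched indices (i1, i2) within one series
#' and charge, computes the observed gap as the charge-corrected difference
#' of the two matched peak m/z values, the peptide positions the gap spans
#' (for c ions, positions i1+1..i2; for z ions the mirrored suffix span), the
#' unmodified mass of those residues under `tab`, and the residual
#' `observed_gap - span_mass`.
#'
#' With `include_origin` an additional gap anchored at the series origin is
#' emitted (`lower_index = 0`): the first matched ion's neutral mass minus
#' the series constant measures the N-terminal residues 1..i directly (for c
#' ions; mirrored for z ions), which is what makes a phosphate on the first
#' or last residue observable at all. Origin gaps use the theoretical series
#' constant as the lower bracket and therefore inherit any calibration
#' offset, unlike interior gaps, which are pure peak differences.
#'
#' @param m a `match_result` (must carry its `peptide`).
#' @param series `"c"` or `"z"`.
#' @param tab mass table for the span mass; defaults to the table the match
#'   was made with. Passing the `"nominal"` table reproduces hand-annotation
#'   arithmetic on 2-decimal average masses.
#' @param charge fragment charge whose matches are used.
#' @param include_origin also emit the origin-anchored gap (see above).
#' @return data.frame with columns `spectrum_id`, `series`, `charge`,
#'   `lower_index`, `upper_index`, `span_start`, `span_end`, `span_seq`,
#'   `span_mass`, `observed_gap`, `residual`. Zero rows when fewer than two
#'   ions of the series are matched.
#' @export
find_bracket_gaps <- function(m, series = "c", tab = NULL, charge = 1L,
                              include_origin = TRUE) {
  stopifnot(inherits(m, "match_result"))
  if (is.null(m$peptide))
    stop("match_result carries no peptide; pass `peptide` to match_spectrum()")
  if (is.null(tab)) tab <- m$tab
  p <- m$peptide
  n <- nchar(p$sequence)
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  a <- m$assignments
  a <- a[a$series == series & a$charge == charge, , drop = FALSE]
  a <- a[order(a$index), , drop = FALSE]
  empty <- data.frame(spectrum_id = character(0), series = character(0),
                      charge = integer(0), lower_index = integer(0),
                      upper_index = integer(0), span_start = integer(0),
                      span_end = integer(0), span_seq = character(0),
                      span_mass = numeric(0), observed_gap = numeric(0),
                      residual = numeric(0))
  if (nrow(a) < 1L || (nrow(a) < 2L && !include_origin)) return(empty)
  out <- list()
  if (include_origin) {
    i1 <- a$index[1]
    constant <- if (series == "c") tab$ammonia else tab$z_dot
    gap <- charge * (a$peak_mz[1] - tab$proton) - constant
    span <- if (series == "c") 1L:i1 else (n - i1 + 1L):n
    smass <- sum(tab$residue[res[span]])
    out[[1L]] <- data.frame(
      spectrum_id = m$spectrum_id, series = series, charge = charge,
      lower_index = 0L, upper_index = i1, span_start = min(span),
      span_end = max(span), span_seq = paste(res[span], collapse = ""),
      span_mass = smass, observed_gap = gap, residual = gap - smass,
      stringsAsFactors = FALSE)
  }
  if (nrow(a) < 2L) return(do.call(rbind, out))
  inner <- lapply(seq_len(nrow(a) - 1L), function(r) {
    i1 <- a$index[r]; i2 <- a$index[r + 1L]
    gap <- charge * (a$peak_mz[r + 1L] - a$peak_mz[r])
    if (series == "c") {
      span <- (i1 + 1L):i2
    } else {
      span <- (n - i2 + 1L):(n - i1)
    }
    smass <- sum(tab$residue[res[span]])
    data.frame(spectrum_id = m$spectrum_id, series = series,
               charge = charge, lower_index = i1, upper_index = i2,
               span_start = min(span), span_end = max(span),
               span_seq = paste(res[span], collapse = ""),
               span_mass = smass, observed_gap = gap,
               residual = gap - smass, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, inner))
}

site_label <- function(residue, protein_pos) sprintf("%s%d", residue, protein_pos)

#' Localize phosphates from bracket gaps
#'
#' Gaps whose residual is within `residual_tol` of `k * phospho_delta`
#' (k = 1..`max_phospho`) are called phosphate-bearing; the candidate sites
#' are the S/T/Y residues in the span, reported as protein coordinates
#' (e.g. `"S320"`). Status is `localized` with exactly one candidate,
#' `ambiguous` with two or more, and `none` (with a diagnostic) when a
#' phosphate-sized residual spans no S/T/Y. Gaps with residual within
#' `residual_tol` of zero are unmodified spans and emit nothing, as do gaps
#' with unexplained residuals.
#'
#' @param gaps data.frame from [find_bracket_gaps()].
#' @param p the [peptide()] the gaps refer to.
#' @param phospho_delta phosphate mass shift to test (Da).
#' @param residual_tol residual tolerance in Da. The default 1.2 reflects
#'   ion-trap gap arithmetic, where residuals around a nominal +80 Da can be
#'   off by close to 1 Da.
#' @param max_phospho maximum phosphates per gap.
#' @return data.frame with columns `spectrum_id`, `series`, `lower_index`,
#'   `upper_index`, `status`, `sites` (";"-separated site labels),
#'   `n_candidates`, `n_phospho`, `observed_gap`, `span_mass`, `residual`,
#'   `diagnostic`.
#' @export
localize_phospho <- function(gaps, p, phospho_delta = 79.96633,
                             residual_tol = 1.2, max_phospho = 1L) {
  stopifnot(residual_tol > 0, max_phospho >= 1)
  res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  out <- list()
  for (r in seq_len(nrow(gaps))) {
    g <- gaps[r, ]
    if (abs(g$residual) <= residual_tol) next  # unmodified span
    devs <- abs(g$residual - (1:max_phospho) * phospho_delta)
    if (min(devs) > residual_tol) next        # unexplained gap
    k <- which.min(devs)
    span <- g$span_start:g$span_end
    cand <- span[res[span] %in% c("S", "T", "Y")]
    coord <- p$protein_start + cand - 1L
    status <- if (length(cand) == 1L) "localized"
              else if (length(cand) >= 2L) "ambiguous" else "none"
    out[[length(out) + 1L]] <- data.frame(
      spectrum_id = g$spectrum_id, series = g$series,
      lower_index = g$lower_index, upper_index = g$upper_index,
      status = status,
      sites = paste(site_label(res[cand], coord), collapse = ";"),
      n_candidates = length(cand), n_phospho = k,
      observed_gap = g$observed_gap, span_mass = g$span_mass,
      residual = g$residual,
      diagnostic = if (status == "none")
        "phosphate-sized residual over a span with no S/T/Y" else "",
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(spectrum_id = character(0), series = character(0),
                      lower_index = integer(0), upper_index = integer(0),
                      status = character(0), sites = character(0),
                      n_candidates = integer(0), n_phospho = integer(0),
                      observed_gap = numeric(0), span_mass = numeric(0),
                      residual = numeric(0), diagnostic = character(0)))
  do.call(rbind, out)
}

#' Verify peptide identity from a matched ion series
#'
#' The identity of a peptide is supported when at least `min_series_count`
#' non-suppressed ions of the series are matched and every unmatched index
#' between the lowest and highest matched index is accounted for: either the
#' ion is suppressed (pre-proline bond, which does not cleave in ETD) or it
#' lies inside a bracket gap whose residual is explained (within
#' `residual_tol` of zero or of `k * phospho_delta`).
#'
#' @param m a `match_result`.
#' @param min_series_count minimum number of matched ions.
#' @param series series to verify on (`"c"` or `"z"`).
#' @param phospho_delta phosphate mass shift; defaults to the match table's.
#' @param residual_tol residual tolerance in Da.
#' @param max_phospho maximum phosphates per gap.
#' @param charge fragment charge.
#' @return list with `verified` (logical), `n_matched`, `matched` (indices)
#'   and `report` (data.frame of interior unmatched indices and the reason
#'   each is accounted for, or `"unexplained"`).
#' @export
verify_identity <- function(m, min_series_count = 7L, series = "c",
                            phospho_delta = NULL, residual_tol = 1.2,
                            max_phospho = 1L, charge = 1L) {
  stopifnot(inherits(m, "match_result"))
  if (is.null(phospho_delta)) phospho_delta <- m$tab$phospho
  idx <- matched_indices(m, series, charge)
  report <- data.frame(index = integer(0), reason = character(0))
  if (length(idx) < 2L) {
    return(list(verified = FALSE, n_matched = length(idx), matched = idx,
                report = report))
  }
  gaps <- find_bracket_gaps(m, series, charge = charge)
  explained <- abs(gaps$residual) <= residual_tol
  for (k in seq_len(max_phospho))
    explained <- explained |
      abs(gaps$residual - k * phospho_delta) <= residual_tol
  un <- m$unmatched
  supp_idx <- un$index[un$series == series & un$suppressed]
  interior <- setdiff(seq(min(idx), max(idx)), idx)
  ok <- TRUE
  for (i in interior) {
    inside <- which(gaps$lower_index < i & gaps$upper_index > i)
    reason <- if (i %in% supp_idx) "suppressed (pre-proline)"
      else if (length(inside) && any(explained[inside])) "inside explained gap"
      else "unexplained"
    if (reason == "unexplained") ok <- FALSE
    report <- rbind(report, data.frame(index = i, reason = reason,
                                       stringsAsFactors = FALSE))
  }
  verified <- ok && length(idx) >= min_series_count
  list(verified = verified, n_matched = length(idx), matched = idx,
       report = report)
}

#' Aggregate site assignments across spectra
#'
#' Per-residue evidence summary: how many assignments localize the site
#' uniquely and how many list it among an ambiguous candidate set. No
#' probabilistic claim is made.
#'
#' @param assignments data.frame rows from [localize_phospho()], possibly
#'   rbind-ed across spectra.
#' @return data.frame with columns `site`, `position`, `n_localized`,
#'   `n_ambiguous`, ordered by protein position.
#' @export
aggregate_sites <- function(assignments) {
  empty <- data.frame(site = character(0), position = integer(0),
                      n_localized = integer(0), n_ambiguous = integer(0))
  if (is.null(assignments) || !nrow(assignments)) return(empty)
  rows <- assignments[assignments$status %in% c("localized", "ambiguous"), ,
                      drop = FALSE]
  if (!nrow(rows)) return(empty)
  per <- lapply(seq_len(nrow(rows)), function(r) {
    data.frame(site = strsplit(rows$sites[r], ";", fixed = TRUE)[[1]],
               status = rows$status[r], stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  sites <- unique(per$site)
  out <- data.frame(
    site = sites,
    position = as.integer(sub("^[A-Z]", "", sites)),
    n_localized = vapply(sites, function(s)
      sum(per$site == s & per$status == "localized"), 1L),
    n_ambiguous = vapply(sites, function(s)
      sum(per$site == s & per$status == "ambiguous"), 1L),
    stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
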