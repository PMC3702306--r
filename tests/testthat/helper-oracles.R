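# Independent brute-force oracles and small generators used across tests.

MONO20 <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

AA20 <- names(MONO20)

# Brute-force tryptic digest: enumerate every substring and keep those whose
# boundaries are valid cleavage points and whose internal missed-cleavage
# count is within bounds. Returns a sorted data.frame(start, sequence).
oracle_digest <- function(sequence, max_missed, min_length = 1L,
                          max_length = nchar(sequence)) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  is_site <- function(i) i >= 1 && i < n && res[i] %in% c("K", "R") &&
    res[i + 1] != "P"
  rows <- list()
  for (from in 1:n) {
    if (!(from == 1 || is_site(from - 1))) next
    for (to in from:n) {
      if (!(to == n || is_site(to))) next
      len <- to - from + 1
      if (len < min_length || len > max_length) next
      internal <- sum(vapply(seq(from, to - 1), is_site, TRUE),
                      na.rm = TRUE)
      if (to == from) internal <- 0
      if (internal > max_missed) next
      rows[[length(rows) + 1]] <- data.frame(
        start = from, sequence = paste(res[from:to], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, nchar(out$sequence)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force nearest-within-tolerance assignment following the documented
# contract: per series, ions in ascending (index, charge) order, each peak
# usable once per series, nearest peak wins, ties to the lower m/z.
oracle_match <- function(peak_mz, ladder, tol) {
  out <- data.frame(series = character(0), index = integer(0),
                    peak_mz = numeric(0))
  for (ser in unique(ladder$series)) {
    sub <- ladder[ladder$series == ser & !ladder$suppressed, , drop = FALSE]
    sub <- sub[order(sub$index, sub$charge), , drop = FALSE]
    avail <- rep(TRUE, length(peak_mz))
    for (r in seq_len(nrow(sub))) {
      best <- NA
      bestd <- Inf
      for (j in seq_along(peak_mz)) {
        if (!avail[j]) next
        d <- abs(peak_mz[j] - sub$mz[r])
        if (d <= tol && (d < bestd ||
                         (d == bestd && peak_mz[j] < peak_mz[best]))) {
          best <- j
          bestd <- d
        }
      }
      if (!is.na(best)) {
        avail[best] <- FALSE
        out <- rbind(out, data.frame(series = ser, index = sub$index[r],
                                     peak_mz = peak_mz[best]))
      }
    }
  }
  out
}

# Random protein sequence with K/R enriched so digests are non-trivial.
random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE,
               prob = ifelse(AA20 %in% c("K", "R"), 2, 1)), collapse = "")
}

digest_df <- function(peps) {
  data.frame(start = vapply(peps, function(p) p$protein_start, 1L),
             sequence = vapply(peps, function(p) p$sequence, ""),
             stringsAsFactors = FALSE)
}

# Paths to the packaged Fra-2 example, matched ETD analysis of one fixture
# spectrum at the calibration-tolerant window used for the worked example.
match_fixture <- function(which = c("s320", "t322"), product_tol = 1.5) {
  which <- match.arg(which)
  fx <- fra2_example()
  tab <- mass_table("monoisotopic")
  p <- peptide(fx$peptide$sequence, fx$peptide$protein_id,
               fx$peptide$protein_start, list(phospho(14, tab)))
  s <- read_mgf(if (which == "s320") fx$mgf_s320 else fx$mgf_t322)[[1]]
  m <- match_spectrum(s, ladder_set(p, tab, 1L, c("c", "z")),
                      product_tol = product_tol, peptide = p, tab = tab)
  list(spectrum = s, match = m, peptide = p, tab = tab)
}
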