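# Seeded ETD spectrum simulator and site-recovery benchmark.

# Deterministic 31-bit seed from strings (polynomial hash mod 2^31 - 1), so
# each simulated spectrum draws from its own stream defined by the global
# seed, the peptide and the config.
str_seed <- function(...) {
  v <- utf8ToInt(paste(c(...), collapse = "|"))
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  as.integer(h)
}

# Run `code` under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Spectrum simulation settings
#'
#' Controls the imperfections of simulated ETD spectra. Defaults emulate an
#' ion-trap acquisition: a 300-1300 m/z scan window for noise peaks, and
#' uninformative intensities (localization is m/z-only).
#'
#' @param dropout_prob probability that a true fragment peak is omitted
#'   (`0 <= p < 1`).
#' @param n_noise_peaks number of uniform random noise peaks.
#' @param mz_jitter_sd Gaussian m/z jitter standard deviation (Da).
#' @param mz_range numeric length-2; noise peak m/z window.
#' @param intensity_model `"uniform"` or `"rank_decay"`.
#' @param seed integer; combined with the peptide and config to derive one
#'   stream per spectrum, so fixtures are individually reproducible.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(dropout_prob = 0, n_noise_peaks = 0L,
                       mz_jitter_sd = 0, mz_range = c(300, 1300),
                       intensity_model = c("uniform", "rank_decay"),
                       seed = 1L) {
  intensity_model <- match.arg(intensity_model)
  stopifnot(dropout_prob >= 0, dropout_prob < 1, mz_jitter_sd >= 0,
            length(mz_range) == 2L, mz_range[1] < mz_range[2],
            n_noise_peaks >= 0)
  structure(list(dropout_prob = dropout_prob,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 mz_jitter_sd = mz_jitter_sd, mz_range = mz_range,
                 intensity_model = intensity_model, seed = as.integer(seed)),
            class = "sim_config")
}

cfg_string <- function(cfg) {
  sprintf("%g|%d|%g|%g|%g|%s|%d", cfg$dropout_prob, cfg$n_noise_peaks,
          cfg$mz_jitter_sd, cfg$mz_range[1], cfg$mz_range[2],
          cfg$intensity_model, cfg$seed)
}

#' Simulate an ETD spectrum of a peptide
#'
#' Generates the non-suppressed c and z-dot ions (1+), drops each
#' independently with `dropout_prob`, jitters the surviving m/z values with
#' Gaussian noise of sd `mz_jitter_sd`, and adds `n_noise_peaks` uniform
#' noise peaks in `mz_range`. The precursor is the peptide's theoretical m/z
#' at `precursor_charge`. Identical peptide + config + seed give an
#' identical spectrum.
#'
#' @param p a [peptide()] (with its modifications, e.g. a planted phosphate).
#' @param tab a [mass_table()].
#' @param cfg a [sim_config()].
#' @param precursor_charge precursor charge for the simulated precursor m/z.
#' @return a [spectrum()].
#' @export
simulate_spectrum <- function(p, tab = mass_table("monoisotopic"),
                              cfg = sim_config(), precursor_charge = 2L) {
  stopifnot(inherits(p, "peptide"), inherits(cfg, "sim_config"))
  mods <- paste(vapply(p$modifications,
                       function(m) sprintf("%s@%d", m$name, m$position), ""),
                collapse = ",")
  stream <- str_seed(cfg$seed, p$sequence, mods, cfg_string(cfg))
  ions <- ladder_set(p, tab, charges = 1L, series = c("c", "z"))
  ions <- ions[!ions$suppressed, , drop = FALSE]
  with_local_seed(stream, {
    keep <- stats::runif(nrow(ions)) >= cfg$dropout_prob
    mzv <- ions$mz[keep]
    if (cfg$mz_jitter_sd > 0)
      mzv <- mzv + stats::rnorm(length(mzv), 0, cfg$mz_jitter_sd)
    int <- switch(cfg$intensity_model,
      uniform = stats::runif(length(mzv), 10, 100),
      rank_decay = 100 / sqrt(sample.int(max(length(mzv), 1L),
                                         length(mzv))))
    if (cfg$n_noise_peaks > 0L) {
      nmz <- stats::runif(cfg$n_noise_peaks, cfg$mz_range[1], cfg$mz_range[2])
      nint <- stats::runif(cfg$n_noise_peaks, 10, 100)
      mzv <- c(mzv, nmz)
      int <- c(int, nint)
    }
    spectrum(
      id = sprintf("sim_%s_%s_%d", p$sequence,
                   if (nzchar(mods)) mods else "unmod", stream),
      precursor_mz = mz(peptide_neutral_mass(p, tab), precursor_charge, tab),
      precursor_charge = precursor_charge,
      peaks = data.frame(mz = mzv, intensity = int),
      metadata = list(SIMULATED = "1"))
  })
}

#' Random test peptide with at least one phospho-acceptor residue
#'
#' Draws residues uniformly from the 20-letter alphabet; if no S/T/Y is
#' drawn, one random position is replaced by S. With `inject_motif` an
#' `SPT` triplet is written at a random interior position, the situation
#' where ETD proline suppression makes neighbouring S/T sites ambiguous.
#' Uses the current RNG stream.
#'
#' @param length_range integer length-2 range of peptide lengths.
#' @param inject_motif plant an `SPT` motif.
#' @return a [peptide()].
#' @export
random_peptide <- function(length_range = c(8L, 18L), inject_motif = FALSE) {
  len <- sample(seq(length_range[1], length_range[2]), 1L)
  aa <- names(.MONO_RESIDUE)
  res <- sample(aa, len, replace = TRUE)
  if (inject_motif) {
    at <- sample(seq_len(len - 2L), 1L)
    res[at:(at + 2L)] <- c("S", "P", "T")
  }
  if (!any(res %in% c("S", "T", "Y")))
    res[sample(len, 1L)] <- "S"
  peptide(paste(res, collapse = ""))
}

#' Phosphosite recovery benchmark on simulated spectra
#'
#' For each simulation config, draws `n_peptides` random peptides, plants one
#' phosphate on a random S/T/Y, simulates the ETD spectrum, and re-localizes
#' the site from scratch via [localize_spectrum()] over all candidate
#' mono-phosphoforms. Reports the fraction of spectra where the planted site
#' is uniquely localized, contained in an ambiguous candidate set, or missed.
#'
#' @param n_peptides peptides per config.
#' @param length_range peptide length range.
#' @param cfg_grid list of [sim_config()]s; each entry's `seed` is replaced
#'   by `seed` so the whole experiment is reproducible from one integer.
#' @param seed integer master seed.
#' @param tab mass table for simulation and analysis.
#' @param product_tol matching tolerance (Da).
#' @param residual_tol gap residual tolerance (Da).
#' @param inject_motif plant `SPT` motifs (see [random_peptide()]).
#' @return data.frame with one row per config: `dropout_prob`,
#'   `mz_jitter_sd`, `n_noise_peaks`, `n`, `localized_correct`,
#'   `ambiguous_correct`, `wrong` (the three fractions sum to 1).
#' @export
recovery_experiment <- function(n_peptides = 200L,
                                length_range = c(8L, 18L),
                                cfg_grid = list(sim_config()), seed = 1L,
                                tab = mass_table("monoisotopic"),
                                product_tol = 0.7, residual_tol = 1.2,
                                inject_motif = FALSE) {
  stopifnot(n_peptides >= 1)
  peps <- with_local_seed(str_seed(seed, "peptides"), {
    lapply(seq_len(n_peptides), function(i) {
      p <- random_peptide(length_range, inject_motif)
      res <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
      sty <- which(res %in% c("S", "T", "Y"))
      site <- if (length(sty) == 1L) sty else sample(sty, 1L)
      peptide(p$sequence, modifications = list(phospho(site, tab)))
    })
  })
  rows <- lapply(cfg_grid, function(cfg) {
    cfg$seed <- as.integer(seed)
    tally <- c(localized_correct = 0L, ambiguous_correct = 0L, wrong = 0L)
    for (p in peps) {
      planted <- p$modifications[[1]]$position
      truth <- site_label(substr(p$sequence, planted, planted),
                          p$protein_start + planted - 1L)
      s <- simulate_spectrum(p, tab, cfg)
      base <- peptide(p$sequence, p$protein_id, p$protein_start)
      cand <- enumerate_phosphoforms(base, 1L, tab)
      loc <- localize_spectrum(s, cand, tab, product_tol = product_tol,
                               residual_tol = residual_tol)$assignments
      tally[classify_recovery(loc, truth)] <-
        tally[classify_recovery(loc, truth)] + 1L
    }
    data.frame(dropout_prob = cfg$dropout_prob,
               mz_jitter_sd = cfg$mz_jitter_sd,
               n_noise_peaks = cfg$n_noise_peaks, n = length(peps),
               localized_correct = unname(tally[1]) / length(peps),
               ambiguous_correct = unname(tally[2]) / length(peps),
               wrong = unname(tally[3]) / length(peps))
  })
  do.call(rbind, rows)
}

# Classify one spectrum's assignments against the planted site label.
classify_recovery <- function(assignments, truth) {
  if (is.null(assignments) || !nrow(assignments)) return("wrong")
  locd <- assignments[assignments$status == "localized", , drop = FALSE]
  if (nrow(locd)) {
    sites <- unique(locd$sites)
    if (identical(sites, truth)) return("localized_correct")
    if (truth %in% sites) return("wrong")  # conflicting unique calls
    return("wrong")
  }
  amb <- assignments[assignments$status == "ambiguous", , drop = FALSE]
  for (r in seq_len(nrow(amb)))
    if (truth %in% strsplit(amb$sites[r], ";", fixed = TRUE)[[1]])
      return("ambiguous_correct")
  "wrong"
}

#' Write a recovery table as TSV
#'
#' @param table data.frame from [recovery_experiment()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_recovery_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
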