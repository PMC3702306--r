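test_that("a theoretical spectrum self-matches with zero error", {
  mono <- mass_table("monoisotopic")
  p <- peptide("GASTPKLYRE")
  lad <- ladder_set(p, mono, 1L, c("c", "z"))
  live <- lad[!lad$suppressed, ]
  s <- spectrum("self", mz(peptide_neutral_mass(p, mono), 2, mono), 2L,
                data.frame(mz = live$mz, intensity = 1))
  m <- match_spectrum(s, lad, 0.7, peptide = p, tab = mono)
  expect_identical(nrow(m$assignments), nrow(live))
  expect_true(all(abs(m$assignments$error) < 1e-12))
  # only suppressed ions remain unmatched
  expect_true(all(m$unmatched$suppressed))
  # empty peak list gives zero matches, not an error
  s0 <- spectrum("empty", 500, 2L, data.frame(mz = numeric(0),
                                              intensity = numeric(0)))
  m0 <- match_spectrum(s0, lad, 0.7, peptide = p, tab = mono)
  expect_identical(nrow(m0$assignments), 0L)
})

test_that("fixture c13 matches the observed 1269.7 peak", {
  an <- match_fixture("s320")
  a <- an$match$assignments
  row <- a[a$series == "c" & a$index == 13, ]
  expect_identical(row$peak_mz, 1269.7)
  expect_identical(matched_indices(an$match, "c"),
                   c(10L, 12L, 13L, 15L, 17L, 18L, 19L))
})

test_that("matching equals the brute-force nearest-within-tolerance oracle", {
  mono <- mass_table("monoisotopic")
  set.seed(4)
  for (i in 1:30) {
    p <- random_peptide(c(6, 16))
    lad <- ladder_set(p, mono, 1L, c("c", "z"))
    # peaks: a jittered subset of true ions plus junk
    live <- lad$mz[!lad$suppressed]
    pk <- c(live[runif(length(live)) < 0.7], runif(8, 100, 2000))
    pk <- sort(pk + rnorm(length(pk), 0, 0.3))
    s <- spectrum("r", 800, 2L, data.frame(mz = pk, intensity = 1))
    m <- match_spectrum(s, lad, 0.7, peptide = p, tab = mono)
    got <- m$assignments[order(m$assignments$series, m$assignments$index),
                         c("series", "index", "peak_mz")]
    rownames(got) <- NULL
    want <- oracle_match(pk, lad, 0.7)
    want <- want[order(want$series, want$index), ]
    rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("equidistant peaks resolve to the lower m/z", {
  mono <- mass_table("monoisotopic")
  p <- peptide("GG")
  lad <- c_ladder(p, mono)
  target <- lad$mz[1]
  s <- spectrum("tie", 200, 1L,
                data.frame(mz = c(target - 0.2, target + 0.2), intensity = 1))
  m <- match_spectrum(s, lad, 0.7, peptide = p, tab = mono)
  expect_identical(m$assignments$peak_mz, target - 0.2)
})

test_that("bracket gaps reproduce hand arithmetic and vanish on theory", {
  an <- match_fixture("s320")
  gaps <- find_bracket_gaps(an$match, "c", tab = mass_table("nominal"))
  g <- gaps[gaps$lower_index == 13 & gaps$upper_index == 15, ]
  expect_equal(g$observed_gap, 265.1, tolerance = 1e-9)
  expect_identical(g$span_seq, "SP")
  expect_equal(g$span_mass, 184.20, tolerance = 1e-9)
  expect_equal(g$residual, 80.90, tolerance = 1e-9)
  # residual additivity holds on every gap
  expect_equal(gaps$observed_gap - gaps$span_mass - gaps$residual,
               rep(0, nrow(gaps)))

  # theoretical spectrum of an unmodified peptide: all residuals ~ 0
  mono <- mass_table("monoisotopic")
  p <- peptide("GASTKLYRE")
  lad <- ladder_set(p, mono, 1L, c("c", "z"))
  s <- spectrum("t", 500, 2L, data.frame(mz = lad$mz[!lad$suppressed],
                                         intensity = 1))
  m <- match_spectrum(s, lad, 0.7, peptide = p, tab = mono)
  for (ser in c("c", "z")) {
    gg <- find_bracket_gaps(m, ser)
    expect_true(all(abs(gg$residual) < 1e-9))
  }
})

test_that("gap masses are charge-corrected for multiply charged fragments", {
  mono <- mass_table("monoisotopic")
  p <- peptide("GASTKLYRE")
  lad <- ladder_set(p, mono, 2L, "c")
  s <- spectrum("z2", 500, 2L, data.frame(mz = lad$mz[!lad$suppressed],
                                          intensity = 1))
  m <- match_spectrum(s, lad, 0.7, peptide = p, tab = mono)
  gg <- find_bracket_gaps(m, "c", charge = 2L)
  expect_true(nrow(gg) > 0)
  expect_true(all(abs(gg$residual) < 1e-9))
})

test_that("interior-gap residuals are invariant to a global calibration shift", {
  mono <- mass_table("monoisotopic")
  p <- peptide("GASTKLYRE", modifications = list(phospho(4, mono)))
  lad <- ladder_set(p, mono, 1L, c("c", "z"))
  mk <- function(delta) {
    s <- spectrum("shift", 500, 2L,
                  data.frame(mz = lad$mz[!lad$suppressed] + delta,
                             intensity = 1))
    m <- match_spectrum(s, lad, 0.7, peptide = p, tab = mono)
    g <- find_bracket_gaps(m, "c")
    g[g$lower_index >= 1, "residual"]
  }
  expect_equal(mk(0.3), mk(0), tolerance = 1e-9)
})

test_that("localization separates unique, ambiguous and impossible spans", {
  nom <- mass_table("nominal")
  up <- match_fixture("s320")
  gaps_up <- find_bracket_gaps(up$match, "c", tab = nom)
  loc_up <- localize_phospho(gaps_up, up$peptide, nom$phospho,
                             residual_tol = 1.2)
  expect_identical(loc_up$status, "localized")
  expect_identical(loc_up$sites, "S320")

  lo <- match_fixture("t322")
  gaps_lo <- find_bracket_gaps(lo$match, "c", tab = nom)
  loc_lo <- localize_phospho(gaps_lo, lo$peptide, nom$phospho,
                             residual_tol = 1.2)
  expect_identical(loc_lo$status, "ambiguous")
  expect_identical(loc_lo$sites, "S320;T322")

  # phosphate-sized residual over a span with no acceptor residue
  g <- data.frame(spectrum_id = "x", series = "c", charge = 1L,
                  lower_index = 2L, upper_index = 4L, span_start = 3L,
                  span_end = 4L, span_seq = "GL",
                  span_mass = 170.1, observed_gap = 250.1, residual = 80.0,
                  stringsAsFactors = FALSE)
  none <- localize_phospho(g, peptide("AAGLAA"), 80.0, residual_tol = 1.2)
  expect_identical(none$status, "none")
  expect_match(none$diagnostic, "no S/T/Y")
  # an unmodified span emits nothing
  g$observed_gap <- 170.2
  g$residual <- 0.1
  expect_identical(nrow(localize_phospho(g, peptide("AAGLAA"), 80.0)), 0L)
})

test_that("identity verification accounts for every missing interior ion", {
  an <- match_fixture("s320")
  v <- verify_identity(an$match, min_series_count = 7)
  expect_true(v$verified)
  expect_identical(v$n_matched, 7L)
  expect_identical(v$report$index, c(11L, 14L, 16L))
  expect_match(v$report$reason[v$report$index == 14], "pre-proline")

  # requiring more ions than observed fails verification
  expect_false(verify_identity(an$match, min_series_count = 8)$verified)

  # zero matches fail
  mono <- mass_table("monoisotopic")
  p <- peptide("GASTKLYRE")
  lad <- ladder_set(p, mono, 1L, "c")
  s0 <- spectrum("none", 500, 2L, data.frame(mz = 3000, intensity = 1))
  m0 <- match_spectrum(s0, lad, 0.7, peptide = p, tab = mono)
  expect_false(verify_identity(m0, 1)$verified)

  # deleting only a suppressed ion's peak keeps identity intact
  p2 <- peptide("GASPKLYRE")
  lad2 <- ladder_set(p2, mono, 1L, "c")
  pk <- lad2$mz[!lad2$suppressed]
  s2 <- spectrum("del", 500, 2L, data.frame(mz = pk, intensity = 1))
  m2 <- match_spectrum(s2, lad2, 0.7, peptide = p2, tab = mono)
  v2 <- verify_identity(m2, min_series_count = 5)
  expect_true(v2$verified)
  expect_match(v2$report$reason, "pre-proline")

  # an unexplained hole breaks verification: drop c4 and pull its bracketing
  # ions apart (each still within matching tolerance, but the c3-c5 gap
  # residual of 1.3 Da is neither zero nor a phosphate)
  lad3 <- ladder_set(p, mono, 1L, "c")
  pk3 <- lad3$mz
  pk3[3] <- pk3[3] - 0.65
  pk3[5] <- pk3[5] + 0.65
  pk3 <- pk3[-4]
  s3 <- spectrum("hole", 500, 2L, data.frame(mz = pk3, intensity = 1))
  m3 <- match_spectrum(s3, lad3, 0.7, peptide = p, tab = mono)
  v3 <- verify_identity(m3, min_series_count = 1)
  expect_false(v3$verified)
  expect_match(v3$report$reason[v3$report$index == 4], "unexplained")
})

test_that("site aggregation counts localized and ambiguous evidence", {
  a1 <- data.frame(spectrum_id = "s1", series = "c", lower_index = 13L,
                   upper_index = 15L, status = "localized", sites = "S320",
                   n_candidates = 1L, n_phospho = 1L, observed_gap = 265.1,
                   span_mass = 184.2, residual = 80.9, diagnostic = "",
                   stringsAsFactors = FALSE)
  a2 <- a1
  a2$spectrum_id <- "s2"
  a2$status <- "ambiguous"
  a2$sites <- "S320;T322"
  agg <- aggregate_sites(rbind(a1, a2))
  expect_identical(agg$site, c("S320", "T322"))
  expect_identical(agg$n_localized, c(1L, 0L))
  expect_identical(agg$n_ambiguous, c(1L, 1L))
  expect_identical(nrow(aggregate_sites(a1[0, ])), 0L)
  # k copies count k times
  agg3 <- aggregate_sites(rbind(a1, a1, a1))
  expect_identical(agg3$n_localized, 3L)
})
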