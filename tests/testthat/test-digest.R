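test_that("trypsin cleaves after K/R but not before proline", {
  peps <- digest("AKRP", digest_params(max_missed_cleavages = 0,
                                       min_length = 1))
  df <- digest_df(peps)
  expect_identical(df$sequence, c("AK", "RP"))
  expect_identical(df$start, c(1L, 3L))

  peps1 <- digest("AKGR", digest_params(max_missed_cleavages = 1,
                                        min_length = 1))
  expect_true(all(c("AKGR", "AK", "GR") %in% digest_df(peps1)$sequence))
  expect_error(digest(""), "empty")
})

test_that("zero-missed-cleavage peptides tile the protein", {
  set.seed(42)
  for (i in 1:5) {
    prot <- random_protein(120)
    peps <- digest(prot, digest_params(max_missed_cleavages = 0,
                                       min_length = 1, max_length = 500))
    expect_identical(paste(digest_df(peps)$sequence, collapse = ""), prot)
  }
})

test_that("digestion matches the brute-force oracle and grows with missed cleavages", {
  set.seed(7)
  for (i in 1:20) {
    prot <- random_protein(sample(40:150, 1))
    counts <- integer(3)
    for (mc in 0:2) {
      got <- digest_df(digest(prot, digest_params(
        max_missed_cleavages = mc, min_length = 1, max_length = 1000)))
      want <- oracle_digest(prot, mc)
      expect_identical(got, want)
      counts[mc + 1] <- nrow(got)
    }
    expect_true(all(diff(counts) >= 0))
  }
  # length filter agrees too
  prot <- random_protein(200)
  got <- digest_df(digest(prot, digest_params(max_missed_cleavages = 2,
                                              min_length = 6,
                                              max_length = 25)))
  expect_identical(got, oracle_digest(prot, 2, 6, 25))
})

test_that("phosphoform enumeration covers all S/T/Y placements", {
  mono <- mass_table("monoisotopic")
  forms <- enumerate_phosphoforms(peptide("ASA"), 1, mono)
  expect_length(forms, 1L)
  expect_identical(forms[[1]]$modifications[[1]]$position, 2L)

  p20 <- peptide("SSSSGDQSSDSLNSPTLLAL")
  forms20 <- enumerate_phosphoforms(p20, 1, mono)
  expect_length(forms20, 9L)  # 8 serines + 1 threonine
  pos <- vapply(forms20, function(f) f$modifications[[1]]$position, 1L)
  expect_identical(pos, sort(pos))  # deterministic ascending order
  # each form's mass is the base mass plus exactly one phosphate
  base_mass <- peptide_neutral_mass(p20, mono)
  for (f in forms20)
    expect_equal(peptide_neutral_mass(f, mono) - base_mass, mono$phospho,
                 tolerance = 1e-12)

  expect_identical(enumerate_phosphoforms(p20, 0)[[1]], p20)
  expect_length(enumerate_phosphoforms(peptide("GG"), 1, mono), 0L)
  expect_length(enumerate_phosphoforms(peptide("GSG"), 2, mono), 0L)
  expect_length(enumerate_phosphoforms(peptide("STY"), 2, mono), 3L)
})

test_that("find_peptide recovers the phosphopeptide behind the 1023.5 precursor", {
  fx <- fra2_example()
  prot <- read_fasta(fx$fasta)
  hits <- find_peptide(prot$sequence, 1023.5, 2, tol = 2.5,
                       protein_id = prot$id)
  seqs <- vapply(hits, function(p) p$sequence, "")
  nmod <- vapply(hits, function(p) length(p$modifications), 1L)
  expect_true(any(seqs == "SSSSGDQSSDSLNSPTLLAL" & nmod == 1L))
  top <- hits[[1]]
  expect_identical(top$sequence, "SSSSGDQSSDSLNSPTLLAL")
  expect_identical(top$protein_start, 307L)
  expect_lt(abs(attr(top, "mz_error")), 0.1)
  # errors sorted ascending by magnitude
  errs <- abs(vapply(hits, function(p) attr(p, "mz_error"), 1.0))
  expect_identical(errs, sort(errs))
  # far beyond any digest product of this protein
  expect_length(find_peptide(prot$sequence, 9999.0, 2, tol = 2.5), 0L)
})

test_that("find_peptide equals exhaustive enumeration over all phosphoforms", {
  mono <- mass_table("monoisotopic")
  set.seed(13)
  for (i in 1:5) {
    prot <- random_protein(80)
    params <- digest_params(max_missed_cleavages = 2, min_length = 4,
                            max_length = 30)
    base <- digest(prot, params)
    all_forms <- unlist(lapply(base, function(bp)
      c(enumerate_phosphoforms(bp, 0, mono),
        enumerate_phosphoforms(bp, 1, mono))), recursive = FALSE)
    target <- mz(peptide_neutral_mass(
      all_forms[[sample(length(all_forms), 1)]], mono), 2, mono)
    want <- Filter(function(f)
      abs(mz(peptide_neutral_mass(f, mono), 2, mono) - target) <= 2.5,
      all_forms)
    got <- find_peptide(prot, target, 2, tol = 2.5, params = params)
    key <- function(f) sprintf("%s@%d:%s", f$sequence, f$protein_start,
                               paste(vapply(f$modifications,
                                            function(m) m$position, 1L),
                                     collapse = ","))
    expect_setequal(vapply(got, key, ""), vapply(want, key, ""))
  }
})

test_that("peptide TSV export round-trips the essential columns", {
  peps <- digest("AKGRMKAAAR", digest_params(max_missed_cleavages = 1,
                                             min_length = 2),
                 protein_id = "P1")
  f <- tempfile(fileext = ".tsv")
  write_peptides_tsv(peps, f)
  df <- read.delim(f)
  expect_identical(nrow(df), length(peps))
  expect_identical(df$sequence[1], digest_df(peps)$sequence[1])
  expect_true(all(c("protein_id", "start", "end", "mods",
                    "neutral_mass") %in% names(df)))
})
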