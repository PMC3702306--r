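---
title: "Phosphosite localization from ETD spectra: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phosphosite localization from ETD spectra: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The procedure

`phosloc` codifies the manual arithmetic by which an analyst localizes a
phosphate on a peptide from an electron transfer dissociation (ETD) MS/MS
spectrum:

1. **Candidate peptides.** The protein is digested in silico with trypsin
   (cleave after K/R, never before P), allowing missed cleavages, and every
   placement of 0..k phosphates on S/T/Y is enumerated. Forms whose
   theoretical precursor m/z falls within the precursor tolerance of the
   observed value are candidates.
2. **Theoretical ladders.** For each candidate, c ions (prefix + NH₃) and
   z• radical ions (suffix + 1.99184 Da) are computed. ETD does not cleave
   the bond N-terminal to proline, so the c/z• ions at pre-proline bonds are
   generated but flagged `suppressed`; keeping them lets downstream code
   *explain* why an ion is absent instead of merely noting the hole.
3. **Matching.** Each non-suppressed ion is assigned the nearest observed
   peak within the product tolerance (assignment details below).
4. **Bracket gaps.** Consecutive matched indices (i₁, i₂) define a gap whose
   observed, charge-corrected mass difference is compared with the summed
   unmodified masses of residues i₁+1..i₂. A residual compatible with zero
   is an unmodified span; a residual compatible with k·(phosphate mass)
   places k phosphates in the span. The S/T/Y residues of the span, reported
   in protein coordinates, are the candidate sites: one candidate gives a
   `localized` call, several give `ambiguous`.
5. **Identity and aggregation.** A peptide's identity is accepted when
   enough series ions match and every hole in the matched range is accounted
   for (suppressed, or inside a mass-explained gap). Evidence is aggregated
   per site across spectra as counts of localized and ambiguous
   observations; no probabilistic score is attached.

The method's key assumption is that the *differences* between observed
ladder peaks are trustworthy even when the absolute calibration drifts:
gaps are computed from observed peak pairs, never from theory, so a
constant m/z offset cancels. Two further assumptions — singly charged
fragments and at most one phosphate per gap by default — match how such
ion-trap spectra are read in practice; both are configurable.

## Mass conventions

Three tables are built in (`mass_table()`):

| kind | residues | phosphate | used for |
|---|---|---|---|
| `monoisotopic` | lightest isotope | 79.96633 | ladders, precursors (default) |
| `average` | abundance-weighted | 79.9799 | low-resolution alternatives |
| `nominal` | average, rounded to 2 dp | 80.00 | reproducing hand annotation |

The default is monoisotopic because observed low-m/z fragments and the 2+
precursor of the packaged example track monoisotopic theory within a few
tenths of a dalton. The `nominal` table exists because spectra are annotated
by hand with 2-decimal average residue masses (S = 87.08, P = 97.12,
T = 101.11) and a flat "+80" for the phosphate; the packaged worked example
reproduces that arithmetic exactly (c13→c15 gap 265.1, span S+P = 184.20,
residual 80.90). The z• constant is derived, not quoted: requiring
complementary c/z• neutrals to sum to the peptide mass plus one hydrogen
gives water + H − NH₃ = 1.991841 Da (monoisotopic). All tables can be
overridden entry-wise from a `key=value` text file.

## Tolerances and defaults

* **Precursor tolerance, 2.5 Da** and **product tolerance, 0.7 Da** — the
  conventional ion-trap search settings; `digest_params()` likewise defaults
  to two missed cleavages.
* **Residual tolerance, 1.2 Da** (`localize_phospho()`). Gap residuals on
  ion-trap data compare a peak-difference against nominal "+80" arithmetic;
  residuals of 80.9 or 79.8 must be accepted as one phosphate. A ±0.7
  window would wrongly reject such textbook cases, hence the wider default
  for this one comparison.
* **Worked-example matching window, 1.5 Da.** The packaged Fra-2 spectra
  exhibit a calibration drift reaching ≈ +1.2 Da at high m/z (their
  annotated c15 sits 1.23 Da above monoisotopic theory while c13 sits only
  0.18 above). Matching those annotated peaks to monoisotopic ladders
  therefore uses `product_tol = 1.5` in the example analyses; the library
  default stays 0.7. This is exactly the situation the gap method is robust
  to — the 265.1 Da bracket difference is unaffected by the drift.
* **Fragment charge 1+** by default, configurable; gap arithmetic
  charge-corrects observed differences.

## Assignment determinism

Matching is deterministic by construction: within a series, ions are
processed in ascending (index, charge) order; each ion takes the nearest
unused peak within tolerance; equidistant peaks resolve to the lower m/z; a
peak may be reused only across different series. Candidate phosphoforms are
ranked by matched-ion count with ties resolved by input order (ascending
precursor error in the pipeline, ascending modification position from the
enumerator). Re-running the pipeline on identical inputs produces
byte-identical reports; only the run log carries a timestamp.

## Origin-anchored gaps

A strict reading of "gaps between consecutive matched ions" makes a
phosphate on the first or last residue invisible: no ion pair brackets it.
The first matched c ion, however, is itself a mass measurement of residues
1..i (its neutral mass minus NH₃), so `find_bracket_gaps()` also emits an
origin-anchored gap with `lower_index = 0` (mirrored for z•). Unlike
interior gaps, origin gaps inherit the spectrum's absolute calibration
offset — they use the theoretical series constant as the lower bracket —
which is acceptable at the low m/z where first ladder ions sit. With both
series and origin gaps, every position of the peptide is coverable, which
is what makes exact recovery on clean synthetic spectra attainable.

## The synthetic-spectrum generator

`simulate_spectrum()` emulates what matters to m/z-based localization on an
ion-trap instrument: the non-suppressed c/z• ladder at 1+, independent peak
dropout, Gaussian m/z jitter, and uniform noise peaks over a 300–1300 m/z
scan window. Intensities are deliberately uninformative (uniform by
default), since the localization arithmetic never reads them. Each spectrum
draws from a private stream derived from (seed, peptide, config), so any
single fixture is reproducible in isolation. An `SPT`-motif injection
option regenerates the characteristic ambiguity of a serine and threonine
flanking a proline, where suppression plus dropout widens the bracket over
both acceptors.

What the generator does **not** emulate: realistic intensity structure,
multiply charged fragments, neutral losses (−98 Da phospho loss, −H₂O,
−NH₃), isotope envelopes, co-isolated chimeric precursors, or calibration
drift that varies with m/z. Passing recovery benchmarks therefore
demonstrate the correctness and noise behaviour of the matching and gap
logic — not instrument-grade identification performance on real data.

`recovery_experiment()` plants one phosphate per random peptide, simulates,
re-localizes from scratch over all candidate phosphoforms, and tabulates
localized-and-correct, ambiguous-containing-correct, and wrong fractions.
The packaged tests run it at 200 peptides per condition (lengths 8–18),
enough that the monotone degradation of accuracy with jitter and dropout is
visible above Monte-Carlo noise while the whole suite stays fast; on clean
spectra recovery is exact at any size.

## The packaged Fra-2 example

No sequence database entry accompanies the original GST-Fra-2 construct, so
the FASTA fixture is a synthetic 326-residue protein whose residues 307–326
are the authentic phosphopeptide `SSSSGDQSSDSLNSPTLLAL`, preceded by an
arginine so trypsin releases it with the correct coordinates (position 14 =
S320, position 16 = T322); making it the protein's C-terminal peptide also
accounts for its non-tryptic C-terminus. The published residue numbering of
this peptide ("317…326" spanning 20 residues) is internally inconsistent;
the fixture adopts the mapping consistent with the named sites and the
package never renumbers user data. In the two MGF fixtures only the bracket
ions carrying the localization arithmetic (c13/c15, and c13/c16 in the
sibling spectrum) plus the precursor are reported observations; the
remaining series peaks are synthetic reconstructions at theoretical
positions, offset to respect each spectrum's observed calibration, as
documented in the files themselves.

## Degenerate inputs and edge behaviour

Empty MGF files yield empty reports (exit 0 in the CLI); spectra without a
precursor candidate, or without any phosphate-bearing gap, produce explicit
`none` rows with a diagnostic. Phosphate-sized residuals over spans with no
S/T/Y are reported as `none` with a diagnostic rather than silently
dropped. Peptides shorter than two residues cannot be fragmented;
enumeration with more phosphates than acceptors returns an empty list (not
an error). All errors on malformed MGF name the offending line.

## Limitations

Localization confidence is categorical (localized / ambiguous / none), not
probabilistic; spectra are taken as centroided peak lists (no
de-isotoping); only trypsin is implemented; semi-tryptic peptides are not
generated; b/y (CID) ladders are available for matching but the gap
localization path is designed around ETD's c/z• pairs.
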