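# phosloc

Phosphorylation-site mapping from electron transfer dissociation (ETD)
tandem mass spectra.

When a kinase substrate is digested with trypsin and the phosphopeptides are
fragmented by ETD, the backbone cleaves at the N–Cα bond: N-terminal
fragments form the **c-ion series** and C-terminal fragments the **z•-ion
series**, and the labile phosphate stays attached. Because the bond
N-terminal to a proline does not cleave in ETD, ladders have predictable
holes. `phosloc` implements the analysis an analyst performs on such
spectra — in-silico digestion, theoretical c/z• ladders, tolerance-based
peak matching, and **bracket-gap localization**: if two matched ladder ions
bracket unobserved cleavage positions and their observed mass difference
exceeds the spanned residues' mass by ≈ 80 Da (HPO₃, 79.966 Da
monoisotopic), a phosphate sits in the span, and the span's S/T/Y residues
are the candidate sites. It is aimed at proteomics analysts who want the
manual "site-determining ion" arithmetic as reproducible, testable code.

## The method

For a peptide of residues $r_1 \dots r_n$ with residue masses $m(r_i)$:

* c ions: $\mathrm{neutral}(c_i) = \sum_{k \le i} m(r_k) + \mathrm{NH_3}$,
  suppressed when $r_{i+1} = \mathrm{P}$;
* z• ions (z+1 radicals):
  $\mathrm{neutral}(z_j) = \sum_{k > n-j} m(r_k) + 1.99184$, so that
  complementary pairs satisfy
  $\mathrm{neutral}(c_i) + \mathrm{neutral}(z_{n-i}) = M + 1.00783$;
* m/z at charge $z$: $(\mathrm{neutral} + z \cdot 1.00728)/z$.

Matched ions $c_{i_1}, c_{i_2}$ ($i_2 > i_1$) define a bracket gap with

$$\Delta_\mathrm{obs} = z\,( \mathrm{m/z}_{i_2} - \mathrm{m/z}_{i_1}), \qquad
\mathrm{residual} = \Delta_\mathrm{obs} - \sum_{k=i_1+1}^{i_2} m(r_k).$$

A residual within tolerance of $k \cdot 80$ Da indicates $k$ phosphates
among positions $i_1{+}1 \dots i_2$; exactly one S/T/Y in the span gives a
`localized` call, several give `ambiguous`. An origin-anchored gap (from the
series constant to the first matched ion) covers sites on the terminal
residues.

## Worked example

The packaged example is the Fra-2 phosphopeptide `SSSSGDQSSDSLNSPTLLAL`
(protein residues 307–326; S320 is peptide position 14, T322 position 16)
with an ETD spectrum of its mono-phosphorylated form (precursor m/z 1023.5,
2+), in which the c-ion series C10, C12, C13, C15, C17, C18 and C19 was
observed — C14 is absent because residue 15 is proline.

```r
library(phosloc)
fx  <- fra2_example()
tab <- mass_table("monoisotopic")
p   <- peptide("SSSSGDQSSDSLNSPTLLAL", "FRA2_SYN", 307,
               list(phospho(14, tab)))
s   <- read_mgf(fx$mgf_s320)[[1]]
m   <- match_spectrum(s, ladder_set(p, tab), product_tol = 1.5,
                      peptide = p, tab = tab)
gaps <- find_bracket_gaps(m, "c", tab = mass_table("nominal"))
gaps[, c("lower_index","upper_index","span_seq","span_mass",
         "observed_gap","residual")]
#>   lower_index upper_index   span_seq span_mass observed_gap residual
#> 1           0          10 SSSSGDQSSD    937.84      937.363 -0.47728
#> 2          10          12         SL    200.24      200.100 -0.14000
#> 3          12          13          N    114.10      114.200  0.10000
#> 4          13          15         SP    184.20      265.100 80.90000
#> 5          15          17         TL    214.27      214.100 -0.17000
#> 6          17          18          L    113.16      113.100 -0.06000
#> 7          18          19          A     71.08       71.000 -0.08000

localize_phospho(gaps, p, 80.0, residual_tol = 1.2)[,
  c("status", "sites", "observed_gap", "span_mass", "residual")]
#>      status sites observed_gap span_mass residual
#> 1 localized  S320        265.1     184.2     80.9
```

Reading the table: the c13→c15 gap measures 265.1 Da where the spanned
residues S+P weigh 184.20 Da (2-decimal average masses, the `"nominal"`
table); the 80.90 Da excess is one phosphate, and since the span's only
phospho-acceptor is the serine at protein position 320, the call is
`localized` at **S320**. Every other gap's residual is ≈ 0, i.e. an
unmodified span. The sibling spectrum (`fx$mgf_t322`) brackets c13→c16
(365.1 observed vs 285.31 for S+P+T, residual 79.79) and spans two
acceptors, so the same arithmetic returns `ambiguous` over S320/T322 —
together the two spectra support phosphorylation of S320 and T322.

The full pipeline (`run_localize()`) does the same from a FASTA plus MGF:
digestion (trypsin, ≤ 2 missed cleavages), precursor search at ±2.5 Da,
ladder matching (±0.7 Da by default; the example above uses 1.5 Da, see the
vignette), gap localization and a per-site evidence report.

## Scope

No intensity modelling, neutral losses, isotope envelopes, probabilistic
localization scores (Ascore-style) or FDR control; CID b/y ladders are
generated behind the same interface but the localization path is ETD-only.
The `vignettes/phosphosite-localization.Rmd` vignette documents the model,
the tolerance choices and the synthetic-spectrum benchmark in detail.
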