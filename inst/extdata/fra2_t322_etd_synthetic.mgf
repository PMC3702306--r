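# Synthetic reconstruction of an ETD spectrum of the mono-phosphorylated
# Fra-2 peptide SSSSGDQSSDSLNSPTLLAL (protein residues 307-326), lower-panel
# reading: C13 and C16 observed, C14/C15 absent, leaving the phosphate
# ambiguous between S320 and T322. The c13 (1269.6) and c16 (1634.7) values
# are the reported observations; the remaining peaks are synthetic, placed
# at monoisotopic theory rounded to 0.1 Da. The precursor m/z of this
# acquisition was not reported and is reused from the sibling spectrum.
# Intensities are arbitrary.
BEGIN IONS
TITLE=fra2_etd_t322
PEPMASS=1023.5
CHARGE=2+
955.4 38
1155.5 63
1269.6 74
1634.7 52
1747.7 41
1860.8 33
1931.8 26
END IONS
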