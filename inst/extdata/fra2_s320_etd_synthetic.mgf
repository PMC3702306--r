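# Synthetic reconstruction of an ETD spectrum of the mono-phosphorylated
# Fra-2 peptide SSSSGDQSSDSLNSPTLLAL (protein residues 307-326), upper-panel
# reading: observed C ion series C10, C12, C13, C15, C17, C18, C19.
# The c13 (1269.7) and c15 (1534.8) values are the reported observations;
# the remaining peaks are synthetic, placed at monoisotopic theory (0.1 Da
# rounding) with the high-m/z ions offset +1.2 Da to match this spectrum's
# calibration as evidenced by its reported c15. Intensities are arbitrary.
BEGIN IONS
TITLE=fra2_etd_s320
PEPMASS=1023.5
CHARGE=2+
955.4 42
1155.5 57
1269.7 88
1534.8 61
1748.9 35
1862.0 47
1933.0 29
END IONS
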