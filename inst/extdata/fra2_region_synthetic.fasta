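>FRA2_SYN synthetic Fos-related antigen 2 context; residues 307-326 are the authentic phosphopeptide region (S320/T322)
LSFEDTYLVQNSRNDFHARFGVERKKLVMHETTHWQVRDMRCFFCLPPADAFIWDGQPEW
NRRRYYHQVYSKPPTESKYFISKQIWRKQPVNLRGFSLDVIFMFCRKVRTYQKKEDKRRA
FYNEVDKDLRDAEPKEMLRFQDHNTWGDFKIRKDPKYTSWAPREKDDNMGAWMKIFALLT
YRPAWTQIADVRWYPRWPYDRGHTTRGGKMTERYAMKDCCIPYPISVPTVATNQNHIYFP
NEIWCKNTYGDLLWRPDCNHCPELNTDYKGCGWFRDHAYLHTEIKPKKTNRNPWSKTTVL
CDYVARSSSSGDQSSDSLNSPTLLAL
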