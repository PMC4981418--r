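>fic_r1
AACGGACGATGCGTGTATGGCTGTGAGACTAAGCTCTACTCGAAACATCTTTCGTGCCACATAAGTGCAAGCTCAATCTA
>sue_r4
AACGGACGATGCGTGTATGGCTGTGAGACTAAGCTCTACTCGAAACATCTTTCGTGCCACATAAGTGCAAGCTCAATCTA
>stc_r7
AACGGACGATGGGTGTATGGCTGTGAGAGTAAGCTCTACTCGACACATCTTTCGTGCCACCTAAGTGCAAGCTCAATGTA
>alb_r12
AACGGACGATGSGTGTATGGCTGTGAGASTAAGCTCTACTCGAMACATCTTTCGTGCCACMTAAGTGCAAGCTCAATSTA
>alb_r15
AACGGACGATGGGTGTATGGCTGTGAGAGTAAGCTCTACTCGACACATCTTTCGTGCCACCTAAGTGCAAGCTCAATGTA
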