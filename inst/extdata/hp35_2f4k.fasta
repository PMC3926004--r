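>villin_headpiece_HP35_double_norleucine_mutant K65Nle K70Nle (X = norleucine)
LSDEDFKAVFGMTRSAFANLPLWXQQHLXKEKGLF
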