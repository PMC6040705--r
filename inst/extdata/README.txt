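# Synthetic stand-in for a sequence-derived HLA-DRB1 typing of the same cohort:
# equals the molecular typing except 3 planted allele mismatches
# (case2 allele2, case6 allele1, case8 allele2).
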