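hexamer	note
ATTAAA	common variant
TATAAA	single-nt variant of AATAAA
AGTAAA	single-nt variant of AATAAA
AAGAAA	single-nt variant of AATAAA
AATATA	single-nt variant of AATAAA
AATACA	single-nt variant of AATAAA
CATAAA	single-nt variant of AATAAA
GATAAA	single-nt variant of AATAAA
AATGAA	single-nt variant of AATAAA
TTTAAA	single-nt variant of AATAAA
ACTAAA	single-nt variant of AATAAA
AATAGA	single-nt variant of AATAAA
ATAAAA	single-nt variant of AATAAA
AAATAA	single-nt variant of AATAAA
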