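# Common laboratory contaminants, matched as case-insensitive substrings
# of the protein id. Extend or replace with a site-specific list.
KRT
TRYP
CON_
ALBU_BOVIN
CAS1_BOVIN
CAS2_BOVIN
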