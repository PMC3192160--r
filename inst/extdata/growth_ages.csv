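specimen,age_yr,provenance
Jane,12,printed
MOR,14,printed_alternative
MOR,16,printed_alternative
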