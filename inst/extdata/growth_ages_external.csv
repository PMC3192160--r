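specimen,age_yr,provenance
Stan,18,external_assumed
Carnegie,22,external_assumed
Sue,28,external_histology
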