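knee_pain:
- 1M10.00
- 1M12.00
- N094W00
- N094611
- N094M00
knee_oa:
- N05z600
- N05zL00
- N051900
imaging:
- 53B..00
- 585f.00
exclusion_ra:
- N040.00
- N040100
exclusion_gout:
- C34..00
- C340.00
exclusion_pseudogout:
- N023.00
exclusion_psa:
- M160000
tkr:
- 7K30500
- 7K30y00
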