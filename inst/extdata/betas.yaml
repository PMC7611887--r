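# Concentration-response coefficients: relative risk of all-cause mortality
# per 10 ug/m3 of long-term exposure, with 95% confidence intervals.
# COMEAP-recommended values.
version: 1
betas:
  NO2:
    beta: 1.023
    ci95: [1.008, 1.037]
  PM2.5:
    beta: 1.060
    ci95: [1.04, 1.08]
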