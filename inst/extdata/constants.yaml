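# Reference doses, tolerable intakes and regulatory maximum levels for
# dietary cadmium. Units are stated per key.
rfd_efsa: 0.36        # ug/kg bw/day, EFSA tolerable daily dose (TWI/7, 2 dp)
twi_efsa: 2.5         # ug/kg bw/week, EFSA tolerable weekly intake
ptwi_jecfa: 7         # ug/kg bw/week, JECFA provisional tolerable weekly intake
ptmi_jecfa: 25        # ug/kg bw/month, JECFA provisional tolerable monthly intake
rfd_epa_water: 0.0005 # mg/kg/day, US EPA reference dose for Cd in water
rfd_epa_food: 0.001   # mg/kg/day, US EPA reference dose for Cd in food
ml_taiwan: 0.4        # mg/kg, maximum level for Cd in rice (Taiwan, Codex)
ml_china: 0.2         # mg/kg, maximum level for Cd in rice (China)
loq_as_printed: 0.2   # mg/kg, limit of quantification as reported by the
                      # source laboratory; inconsistent with an 89% detection
                      # rate at a 0.04 mg/kg mean, so not used as the default
                      # censoring threshold (see default_censor_threshold)
default_censor_threshold: 0.002 # mg/kg, working censor point for synthesis
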