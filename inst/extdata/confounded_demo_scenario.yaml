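# Synthetic latent-confounder demonstration scenario (same as demo_scenario()):
# within each observed stratum v the exposure assignment and the risks both
# depend on the latent u, so standardization over v alone is biased.  All
# cells share a true risk ratio of 0.5.
cells:
- v: v1
  u: u1
  prevalence: 0.25
  risk_untreated: 0.2
  risk_treated: 0.1
  assignment: 0.8
- v: v1
  u: u2
  prevalence: 0.25
  risk_untreated: 0.6
  risk_treated: 0.3
  assignment: 0.2
- v: v2
  u: u1
  prevalence: 0.25
  risk_untreated: 0.3
  risk_treated: 0.15
  assignment: 0.7
- v: v2
  u: u2
  prevalence: 0.25
  risk_untreated: 0.7
  risk_treated: 0.35
  assignment: 0.3
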