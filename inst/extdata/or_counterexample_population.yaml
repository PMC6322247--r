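# Randomized-trial population illustrating odds-ratio non-collapsibility:
# both strata have causal OR 3, the marginal causal OR is 2.83.
strata:
- label: men
  prevalence: 0.25
  risk_untreated: 0.5
  risk_treated: 0.75
- label: women
  prevalence: 0.75
  risk_untreated: 0.25
  risk_treated: 0.5
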