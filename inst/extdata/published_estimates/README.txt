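Inputs for re-deriving the published mediation proportions for MET.

beta_step2 (protein on outcome, log-OR) and total (per-cluster total
effect, log-OR) are the printed per-protein and per-cluster MR
estimates. beta_step1 (cluster-scaled exposure effect on MET) is
DERIVED, not printed: it is back-formed as mediated / beta_step2 from
the printed mediated proportions and totals (the supplementary table
carrying the step-1 estimates is not redistributed here). printed_pct
is the published proportion mediated, in percent (magnitude).
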