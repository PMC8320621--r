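# Standardized respiratory clinical-sign lexicon and synonym map.
# Raw dossier wordings (case-insensitive) map to one of the six lexicon
# terms; anything else is reported as unmapped. Edit freely: the mapping is
# configuration, not code.
terms:
  - irregular respiration
  - shallow respiration
  - noisy respiration
  - slow respiration
  - rapid/fast respiration
  - gasping
synonyms:
  rapid respiration: rapid/fast respiration
  fast respiration: rapid/fast respiration
  tachypnoea: rapid/fast respiration
  tachypnea: rapid/fast respiration
  hyperpnoea: rapid/fast respiration
  hyperpnea: rapid/fast respiration
  bradypnoea: slow respiration
  bradypnea: slow respiration
  slow breathing: slow respiration
  decreased respiratory rate: slow respiration
  irregular breathing: irregular respiration
  dyspnoea: irregular respiration
  dyspnea: irregular respiration
  laboured respiration: irregular respiration
  labored respiration: irregular respiration
  shallow breathing: shallow respiration
  rales: noisy respiration
  audible respiration: noisy respiration
  wheezing: noisy respiration
  gasps: gasping
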