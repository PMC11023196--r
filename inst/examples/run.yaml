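# One farm scenario: 20% farm area as several small clusters, attraction 5,
# strong (MSY) management, calibrated default species.
species:
  range_fraction: 0.28
fishery:
  regime: strong
farm:
  total_fraction: 0.2
  layout: several_small
  attraction: 5
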