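# A small sweep for `oceanfarm sweep`.
farm_fractions: [0.1, 0.2, 0.4]
attraction_levels: [1, 5, 15]
regimes: [strong, weak]
layouts: [several_small, one_large]
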