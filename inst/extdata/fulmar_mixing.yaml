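# Mixing distribution of fledglings over the latent heterogeneity groups,
# estimated for ordinary sea-ice conditions.
groups: [UH-1, UH-2, UH-3]
mixing: [0.14, 0.67, 0.19]
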