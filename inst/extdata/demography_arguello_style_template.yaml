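# Structural template for a three-population history with an Ithaca, New York
# focal population founded by admixture and held at constant size
# post-admixture. Sizes and event times marked EXTERNAL must be filled in
# from the posterior modes of the published model fit; this package does not
# assert those values. Only the mutation rate and the rescaling factor
# conventionally used with this model are pre-filled.
external_parameters: true
mutation_rate: 1.39e-9      # per site per generation
Q: 100                      # rescaling factor conventionally applied
sample_n: 145
focal_pop: ithaca
demes:
  - name: africa
    size: EXTERNAL          # ancestral (Zimbabwe) diploid size, = N_anc of the DFE
  - name: europe
    size: 0
  - name: ithaca
    size: 0
events:
  - type: split
    time: EXTERNAL
    source: africa
    deme: europe
    size: EXTERNAL
  - type: admixture
    time: EXTERNAL          # founding of the Ithaca population
    deme: ithaca
    sources:
      africa: EXTERNAL
      europe: EXTERNAL
    size: EXTERNAL          # current size; held constant post-admixture
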