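# Structural template for a three-population out-of-Africa style history of
# D. melanogaster (African ancestral population, European split, North
# American Raleigh population founded by an admixture pulse and held at
# constant size post-admixture).
#
# Numeric sizes and event times are NOT asserted by this package: the values
# marked EXTERNAL must be filled in from the posterior modes of the published
# model fit before the template can be simulated. Only the mutation rate and
# the rescaling factor conventionally used with this model are pre-filled.
external_parameters: true
mutation_rate: 1.0e-9       # per site per generation
Q: 300                      # rescaling factor conventionally applied
sample_n: 145
focal_pop: raleigh
demes:
  - name: africa
    size: EXTERNAL          # ancestral (Zimbabwe) diploid size, = N_anc of the DFE
  - name: europe
    size: 0
  - name: raleigh
    size: 0
events:
  - type: split
    time: EXTERNAL          # forward-time generation of the Europe split
    source: africa
    deme: europe
    size: EXTERNAL
  - type: admixture
    time: EXTERNAL          # founding of the Raleigh population
    deme: raleigh
    sources:
      africa: EXTERNAL      # admixture proportions, summing to 1
      europe: EXTERNAL
    size: EXTERNAL          # current size; held constant post-admixture
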