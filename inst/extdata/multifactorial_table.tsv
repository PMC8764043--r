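# Multifactorial classification inputs for the two recurrently-sampled VUS:
# prior probability of pathogenicity and component likelihood ratios
# (co-segregation, tumor pathology, family history), with the published
# combined odds and posterior for reference. The c.5497G>A published odds
# value is not the product of its published LRs (internal inconsistency in
# the source table); its row is carried for completeness but not used as a
# numerical reference.
variant_id	prior	lr_cosegregation	lr_pathology	lr_family_history	published_odds	published_posterior
c.4963T>C	0.03	68.44	152.88	8.71	91176.32	0.99965
c.5497G>A	0.03	7.858	1480.48	272.76	442.75	0.99865
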