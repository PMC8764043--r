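# Default simulation conditions for a synthetic carrier cohort.
# Class-conditional second-hit rates are the observed combined-cohort rates
# (loss of WT: 36/55 pathogenic, 6/27 benign; loss of variant: 3/55, 4/27);
# purity spans the cellularity range of the worked family (30-90%).
n_variants_per_class: 4
samples_per_variant: 5
p_loss_wt_by_class:
  PATHOGENIC: 0.654
  BENIGN: 0.222
p_loss_variant_by_class:
  PATHOGENIC: 0.055
  BENIGN: 0.148
purity_range: [0.3, 0.9]
read_depth: 1000
pyro_sd: 0.02
replicates: 3
copy_model: DELETION
subclonal_fraction_range: [1.0, 1.0]
method: PYRO
seed: 20220117
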