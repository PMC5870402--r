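# Analysis recipe for the flu-vaccine study pipeline: difference-score
# predictors, maximal baseline-corrected HAI outcome, stability-selected
# sparse principal covariates regression with two components.
#
# Provenance of the public expression data (not downloaded by this package):
# GEO accessions GSE29614 (2007 season, test) and GSE29617 (2008 season,
# training).  Point the paths below at RMA-processed expression matrices
# (subjects x probesets) and a titer table (subject, assay, baseline, day28).

baseline_expression = data/expression_baseline.csv
day3_expression = data/expression_day3.csv
titers = data/titers.csv
output_dir = results/flu

n_components = 2
alpha = 0.99
lambda2_frac = 0.05        # ridge penalty as a fraction of the lasso value
loading_constraint = unit_length
drop_constant = true       # drop probesets with constant difference scores

n_resamples = 500
resample_fraction = 0.5
pi_threshold = 0.90
expected_false = 1
grid_size = 50
seed = 1
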