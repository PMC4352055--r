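# Example run configuration for the cogmap CLI / workflows.
# Omitted keys take the documented defaults.
task: algebra
n_subjects: 18
n_trials: 8
seed: 1
tr: 2
sigma: 1.0
noise_kind: white
radius_mm: 12
p_thresh: 1.0e-7
min_extent: 50        # extent at 4 mm voxels (~250 at 2.5 mm resolution)
target_size: 100
connectivity: 26
window: 18
drift_order: 1
accuracy_cutoff: 0.85
rt_sd_cutoff: 2
hrf:
  peak_shape: 6
  undershoot_shape: 16
  undershoot_ratio: 0.16666667
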