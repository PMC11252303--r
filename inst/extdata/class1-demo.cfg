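# helixline pipeline configuration (key = value, one per line).
# Simulates a short-crossover filament at snr 1, measures its layer lines,
# classifies it, reconstructs it and docks the generating model.
preset = class1
n_subunits = 120
voxel_size = 5
resolution = 20
snr = 1
wedge_half_angle = 60
recon_units = 20
fit_model = TRUE
outdir = helixline_run
seed = 0
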