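# Shared fixtures, built once per test run and cached in-memory. All
# fixtures are generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# noiseless renders of the two presets (the workhorses of most tests)
class1_volume <- function() fixture("class1_volume",
  render_filament(class1_filament_spec()))

canonical_volume <- function() fixture("canonical_volume",
  render_filament(canonical_filament_spec()))

class1_projection <- function() fixture("class1_projection",
  project_filament(class1_volume()))

canonical_projection <- function() fixture("canonical_projection",
  project_filament(canonical_volume()))

class1_lines <- function() fixture("class1_lines",
  detect_layer_lines(compute_power_spectrum(class1_projection())))

canonical_lines <- function() fixture("canonical_lines",
  detect_layer_lines(compute_power_spectrum(canonical_projection())))

# microtubule renders for the protofilament tests
microtubule_volume <- function(n) fixture(paste0("mt", n),
  render_density(build_microtubule_model(microtubule_spec(n, length = 400)),
                 voxel_size = 5, box = c(64, 64, 80), resolution = 20))

# measure a filament crossover (A) from a noisy render of `spec`
measure_noisy_crossover <- function(spec, seed, snr = 1) {
  v <- add_noise_and_wedge(render_filament(spec),
                           noise_model(snr = snr, seed = seed))
  ll <- detect_layer_lines(compute_power_spectrum(
    project_filament(crop_to_object(v))))
  if (nrow(ll) == 0) return(NA_real_)
  derive_helical_parameters(ll)$crossover
}

classify_noisy <- function(spec, seed, snr = 1) {
  cx <- measure_noisy_crossover(spec, seed, snr)
  if (!is.finite(cx)) return("NONE")
  classify_filament(list(crossover = cx))
}

# annotation table reproducing the in-situ length totals (22.7 um of
# lumenal filament across 82.7 um of microtubule)
situ_annotation_table <- function() {
  fil_lengths <- c(rep(0.45, 40), rep(0.188, 25))   # 18 + 4.7 = 22.7 um
  data.frame(
    tomogram_id = rep(1:5, length.out = 70),
    object_id = c(paste0("f", 1:65), paste0("m", 1:5)),
    object_kind = c(rep("filament", 65), rep("microtubule", 5)),
    class_label = c(rep("CLASS_I", 40), rep("CANONICAL", 25), rep("", 5)),
    length_um = c(fil_lengths, rep(82.7 / 5, 5)),
    host_microtubule_id = NA)
}

# irregular elongated model for transform-recovery tests; elongation keeps
# the orientation well conditioned at low resolution (a near-spherical blob
# has an almost flat rotational correlation landscape)
blob_model <- function(n = 20, seed = 42) {
  set.seed(seed)
  steps <- matrix(stats::rnorm(3 * n, sd = 6), n, 3)
  xyz <- apply(steps, 2, cumsum)
  xyz[, 1] <- xyz[, 1] + seq(0, 60, length.out = n)
  atomic_model(sweep(xyz, 2, colMeans(xyz)))
}

# evaluate expr with a fixed RNG seed without disturbing the session RNG
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
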