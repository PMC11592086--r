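# Shared fixtures: default parameter sets and a lazily built reduced
# muscle model reused across test files.

.fixtures <- new.env()

fix_hill <- function() hill_parameters()
fix_muscle <- function() huxley_parameters()

fix_model <- function() {
  if (is.null(.fixtures$model))
    .fixtures$model <- build_muscle_model(fix_muscle(), fix_hill())
  .fixtures$model
}

fix_demo <- function(seed = 1) {
  key <- paste0("demo", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- demo_objects(seed = seed)
  .fixtures[[key]]
}

# constant-level emg recording built without the generator (for filter
# oracles)
make_emg <- function(x, rate = 200) {
  structure(list(time = seq(0, by = 1 / rate, length.out = length(x)),
                 channels = matrix(x, ncol = 1), rate = rate),
            class = "emg_recording")
}

# a small, fast grasp scenario sharing the cached muscle model
small_scenario <- function(seed = 7, stiffness = 800, duration = 2,
                           surface_shift = 0, ...) {
  links <- finger_links()
  map <- linear_coupling()
  geom <- contact_geometry()
  surf <- sum(c(0, 1) * contact_point(coupled_configuration(0.5, map),
                                      geom, links)$p) + surface_shift
  grasp_scenario(
    object = object_model(surf, stiffness, "test object"),
    profile = activation_profile(c(0, 0.05, 0.35, duration),
                                 c(0, 0, 0.1, 0.1)),
    seed = seed, links = links, map = map, geom = geom,
    model = fix_model(), k_max = 1200, label = "test", ...)
}
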