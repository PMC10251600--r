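# Shared fixtures, built lazily and cached for the whole test run.
# The "panel" fixture (500-compound library + features) is the expensive one;
# only the tests that need study-scale data touch it.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 60-compound library + features: cheap, used by most structural tests
small_library <- function() cached("small_lib", function() {
  generate_library(60, seed = 7)
})

small_features <- function() cached("small_feat", function() {
  build_feature_matrix(data.frame(standardized_smiles = small_library()))
})

# study-scale fixture: 500 compounds, features computed once
panel_library <- function() cached("panel_lib", function() {
  generate_library(500, seed = 101)
})

panel_features <- function() cached("panel_feat", function() {
  build_feature_matrix(data.frame(standardized_smiles = panel_library()))
})

# 3-target SAR panel at the default study conditions (noise_sd 0.3)
panel_sim <- function() cached("panel_sim", function() {
  simulate_activities(panel_library(), targets = paste0("T", 1:3),
                      noise_sd = 0.3, seed = 102,
                      features = panel_features())
})

# a raw record table with every artifact type, for curation tests
raw_table <- function() cached("raw_table", function() {
  lib <- small_library()
  sim <- simulate_activities(lib, targets = "T1", noise_sd = 0.3, seed = 8,
                             features = small_features())
  inject_artifacts(sim$records, seed = 9)
})

# a deterministic constant-prediction model, handy for profiling tests
constant_model <- function(value, train_similarity) {
  structure(list(algorithm = "MLR",
                 config = list(),
                 fit = list(coef = rep(0, 2059), mu = rep(0, 2059),
                            intercept = value),
                 ridge_stabilized = FALSE, seed = 1,
                 feature_names = NULL,
                 train_similarity = train_similarity),
            class = "tuned_model")
}
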