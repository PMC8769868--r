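# Shared fixtures: small planted tables built in code at test time.

tiny_table <- function(seed = 1, n_subjects = 5, n_recordings = 10,
                       d = 6, informative = c(1, 2), effect_size = 5,
                       noise_sd = 1, p = 3) {
  generate_feature_table(
    plant_spec(n_subjects, n_recordings, d, informative,
               effect_size = effect_size, noise_sd = noise_sd, seed = seed),
    coeffs_per_channel = p)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

quiet <- function(expr) suppressWarnings(expr)
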