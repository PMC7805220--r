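# Communities are expensive; build each configuration once per test run.
.comm_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .comm_cache))
    assign(key, force(expr), envir = .comm_cache)
  get(key, envir = .comm_cache)
}

# small community exercising every feature quickly
small_spec <- function(seed = 7) {
  community_spec(n_groups = 2, genomes_per_group = 2, n_virophages = 2,
                 n_background = 3, n_integrations = 2,
                 genome_length_range = c(10000, 20000), seed = seed)
}

small_comm <- function() cached("small", generate_community(small_spec()))

# the default community of the study conditions (seed 42)
default_comm <- function() cached("default",
                                  generate_community(community_spec()))

default_detection <- function() cached("default_det",
                                       run_detection(default_comm()))

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
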