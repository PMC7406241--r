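# Shared fixtures: frozen compartment states and small parameter sets.

# default kinetics used by rate-law unit tests
params_unit <- function(...) {
  golgi_params(n_target = 300, t_max = 10, t_burn = 1, ...)
}

# three hand-built frozen states of increasing heterogeneity, used by the
# frozen-state sampling oracle
frozen_states <- function() {
  list(
    # one mixed compartment plus a cis vesicle
    compartment(n_cis = c(3, 1), n_medial = c(2, 0), n_trans = c(5, 0)),
    # pure compartments of each identity (homotypic-only fusion channels)
    compartment(n_cis = c(6, 0, 0), n_medial = c(0, 4, 0),
                n_trans = c(0, 0, 8)),
    # crowded heterogeneous state with vesicles and cargo
    compartment(n_cis = c(2, 0, 1, 5, 0), n_medial = c(2, 1, 0, 0, 3),
                n_trans = c(1, 4, 0, 0, 3), cargo = c(2, 0, 0, 1, 0))
  )
}

# random valid compositions on the simplex (for property-style tests)
random_compositions <- function(n, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rexp(3 * n), ncol = 3)
  x / rowSums(x)
}

# engine-facing parameter list
engine_params <- function(params, ...) {
  golgisim:::params_for_engine(params, ...)
}
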