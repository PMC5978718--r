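# Shared simulation helpers for the test suite.

# Ordinal draws from a proportional-odds model with cutpoints theta and
# latent mean eta (logit link).
sim_ordinal <- function(eta, theta) {
  u <- stats::runif(length(eta))
  cum <- vapply(theta, function(th) stats::plogis(th - eta),
                numeric(length(eta)))
  cum <- matrix(cum, nrow = length(eta))
  1L + rowSums(u > cum)
}

# Fabricate a density_region object with a known mask on a given grid
# (for set-algebra tests that need exact, hand-checkable regions).
fake_region <- function(mask, x, y) {
  dens <- ifelse(mask, 1, 0)
  structure(list(x = x, y = y, density = dens, mask = mask,
                 threshold = 0.5, H = diag(2), coverage = 0.99,
                 n = sum(mask)),
            class = "density_region")
}

# A small world shared by several tests (20 populations).
small_world <- function(seed = 5) {
  make_world(world_config(
    seed = seed, n_native_pops = 5, n_source_pops = 2,
    n_invaded_pops = c(wNA = 5, eNA = 5, EU = 5)))
}
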