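# Shared fixtures: a default synthetic cycle, the scaled generating
# parameters, and small hand-built tracks. Everything is built in code.

fixture_params <- function() scale_production_rates(e2_params())

fixture_cycle <- function(seed = 1, ...) {
  generate_cycle(synthetic_cycle_spec(seed = seed, ...))
}

# Hand-built three-follicle day: healthy 4, 6 and 9 mm
fixture_simple_tracks <- function() {
  list(follicle_track("a", 0:2, c(4, 4, 4)),
       follicle_track("b", 0:2, c(6, 6, 6)),
       follicle_track("c", 0:2, c(9, 9, 9)))
}

# Forcing with fixed class volumes and a set of atretic dominants
constant_forcing <- function(ReF = 0, SeF = 0, DmF = 0,
                             atr_volume = numeric(), atr_delay = numeric()) {
  n <- length(atr_volume)
  function(t) {
    list(ReF = ReF, SeF = SeF, DmF = DmF,
         atretic_dominants = list(
           follicle_id = as.character(seq_len(n)),
           volume = atr_volume, delay = atr_delay,
           active = rep(TRUE, n),
           age = pmax(1L, as.integer(floor(t - atr_delay)) + 1L)))
  }
}

zero_forcing <- function() constant_forcing()

constant_p4 <- function(level) function(t) rep(level, length(t))

# Random volumes list for RHS identity checks
random_volumes <- function(n_atr = 2) {
  list(ReF = runif(1, 0, 1), SeF = runif(1, 0, 1), DmF = runif(1, 0, 1),
       atretic_dominants = list(
         follicle_id = as.character(seq_len(n_atr)),
         volume = runif(n_atr, 0, 1),
         delay = sample(0:5, n_atr, replace = TRUE),
         active = rep(TRUE, n_atr),
         age = integer(n_atr)))
}
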