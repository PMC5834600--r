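# Shared configuration for the analysis scripts.
#
# The simulated screen mirrors the design of the original experiment:
# four 96-well plates carrying 356 marker antibodies and 9 isotype
# controls, two populations pooled 1:1 per well, 50,000 events per well,
# three paired donors. Thirteen markers are planted as enriched in the
# labelled (PLT) population at 2.5-fold, 51 as equally highly expressed,
# the remainder negative.

library(lyoscreen)

SCREEN_SEED <- 1L
RESULTS_DIR <- "results"

make_screen_config <- function(seed = SCREEN_SEED) {
  plate_sim_config(seed = seed)
}

make_gate_config <- function() {
  gate_config()
}

make_screen_stats_config <- function() {
  screen_config()
}

dir.create(RESULTS_DIR, showWarnings = FALSE)
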