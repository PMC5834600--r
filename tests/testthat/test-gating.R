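# One simulated well reused across gating oracle checks
sim_gating_well <- function(events_per_well = 20000, debris = 0.05,
                            doublet = 0.04, viability = 0, seed = 11L) {
  pops <- default_populations(viability_positive_fraction = viability)
  cfg <- tiny_config(events_per_well = events_per_well,
                     debris_fraction = debris, doublet_fraction = doublet,
                     populations = pops, seed = seed)
  w <- first_marker_well(cfg$layout)
  simulate_well(cfg, w$well, w$plate, "D1")
}

binom_3se <- function(p, n) 3 * sqrt(p * (1 - p) / n)

test_that("acquisition QC enforces the minimum event count", {
  cfg <- gate_config()
  ev <- matrix(1, nrow = 9999, ncol = 1, dimnames = list(NULL, "FSC-A"))
  expect_false(qc_well(ev, cfg)$pass)
  ev <- matrix(1, nrow = 10000, ncol = 1, dimnames = list(NULL, "FSC-A"))
  expect_true(qc_well(ev, cfg)$pass)
  empty <- ev[0, , drop = FALSE]
  res <- qc_well(empty, cfg)
  expect_false(res$pass)
  expect_match(res$reason, "empty well")
})

test_that("scatter gate removes planted debris at its planted rate", {
  sim <- sim_gating_well(debris = 0.05, doublet = 0)
  kept <- gate_cells(sim$events, tiny_gate_config())
  retained <- attr(kept, "retained_fraction")
  expect_lt(abs(retained - 0.95), binom_3se(0.95, nrow(sim$events)))
  # the removed events are overwhelmingly true debris
  removed <- setdiff(seq_len(nrow(sim$events)), attr(kept, "kept"))
  expect_gt(mean(sim$labels$class[removed] == "debris"), 0.98)
})

test_that("scatter gate retains everything when no debris is planted", {
  sim <- sim_gating_well(debris = 0, doublet = 0)
  kept <- gate_cells(sim$events, tiny_gate_config())
  expect_gt(attr(kept, "retained_fraction"), 0.999)
})

test_that("a fixed scatter threshold above all events hits the empty-gate path", {
  sim <- sim_gating_well(events_per_well = 2000, debris = 1e-6, doublet = 0)
  cfg <- tiny_gate_config(scatter_gate = list(method = "fixed",
                                              threshold = 1e9))
  expect_warning(kept <- gate_cells(sim$events, cfg), "empty gate")
  expect_equal(nrow(kept), 0)
})

test_that("doublet exclusion removes the planted doublet fraction", {
  sim <- sim_gating_well(debris = 0, doublet = 0.04)
  kept <- exclude_doublets(sim$events, tiny_gate_config())
  expect_lt(abs(attr(kept, "removed_fraction") - 0.04),
            binom_3se(0.04, nrow(sim$events)))
  sim0 <- sim_gating_well(debris = 0, doublet = 0)
  kept0 <- exclude_doublets(sim0$events, tiny_gate_config())
  expect_lt(attr(kept0, "removed_fraction"), 0.01)
})

test_that("perfectly proportional FSC-H keeps every event", {
  set.seed(3)
  fa <- stats::runif(500, 1e4, 9e4)
  ev <- cbind(`FSC-A` = fa, `FSC-H` = 0.9 * fa)
  kept <- exclude_doublets(ev, tiny_gate_config())
  expect_equal(attr(kept, "removed_fraction"), 0)
})

test_that("doublet fit is skipped with a warning on tiny inputs", {
  ev <- cbind(`FSC-A` = stats::runif(10, 1, 2), `FSC-H` = stats::runif(10))
  expect_warning(kept <- exclude_doublets(ev, tiny_gate_config()),
                 "fewer than 50")
  expect_equal(nrow(kept), 10)
})

test_that("viability gate removes planted dead cells at the control quantile", {
  sim <- sim_gating_well(debris = 0, doublet = 0, viability = 0.1)
  ctrl <- sim_gating_well(debris = 0, doublet = 0, viability = 0, seed = 12L)
  cfg <- tiny_gate_config()
  kept <- exclude_dead(sim$events, ctrl$events, cfg)
  expect_lt(abs(attr(kept, "removed_fraction") - 0.1),
            binom_3se(0.1, nrow(sim$events)) + 0.001)
  # control identical to sample at 0.999 -> ~0.1% removed (strict-above rule)
  kept2 <- exclude_dead(ctrl$events, ctrl$events, cfg)
  expect_lt(attr(kept2, "removed_fraction"), 0.0011)
  # all events at/below the threshold -> identity
  low <- ctrl$events
  low[, "DAPI-A"] <- 1
  expect_equal(nrow(exclude_dead(low, ctrl$events, cfg)), nrow(low))
})

test_that("demultiplexing a 1:1 pool recovers half the events per population", {
  sim <- sim_gating_well(events_per_well = 50000, debris = 0, doublet = 0)
  dm <- demultiplex_barcode(sim$events, tiny_gate_config())
  n <- nrow(sim$events)
  frac_pos <- nrow(dm$positive) / n
  expect_lt(abs(frac_pos - 0.5), binom_3se(0.5, n))
  # partition is exhaustive and disjoint
  expect_equal(nrow(dm$positive) + nrow(dm$negative), n)
  expect_length(intersect(attr(dm$positive, "kept"),
                          attr(dm$negative, "kept")), 0)
  # assignments agree with the planted population labels
  pos_pops <- sim$labels$population[attr(dm$positive, "kept")]
  expect_gt(mean(pos_pops == "PLT"), 0.999)
})

test_that("a fully labelled well is judged unimodal", {
  set.seed(5)
  ev <- cbind(`CTV-A` = stats::rlnorm(20000, log(5000), 0.35))
  expect_error(demultiplex_barcode(ev, tiny_gate_config()),
               "judged unimodal")
})

test_that("overlapping barcode modes reproduce the two-Gaussian Bayes error", {
  pops <- barcode_overlap_preset(default_populations(), sep = 2)
  cfg <- tiny_config(events_per_well = 50000, populations = pops, seed = 21L)
  w <- first_marker_well(cfg$layout)
  sim <- simulate_well(cfg, w$well, w$plate, "D1")
  dm <- demultiplex_barcode(sim$events, tiny_gate_config())
  truth_pop <- sim$labels$population
  called <- rep("FCS", nrow(sim$events))
  called[attr(dm$positive, "kept")] <- "PLT"
  mis <- mean(called != truth_pop)
  # closed-form equal-prior equal-variance misassignment: Phi(-sep/2)
  bayes <- stats::pnorm(-1)
  expect_lt(abs(mis - bayes), binom_3se(bayes, nrow(sim$events)))
})

test_that("positivity gate is the interpolated order-statistic quantile", {
  # brute-force type-7 oracle on the 1..1000 grid:
  # h = 1 + 0.999*(1000-1) = 999.001 -> x[999] + 0.001*(x[1000]-x[999])
  expect_equal(set_positivity_gate(1:1000, 0.999), 999.001)
  expect_equal(set_positivity_gate(rep(7, 200), 0.999), 7)
  expect_error(set_positivity_gate(1:99, 0.999), "gate error")
  # gate threshold monotone non-decreasing in confidence
  set.seed(8)
  x <- stats::rlnorm(5000, 4, 0.7)
  confs <- c(0.5, 0.9, 0.99, 0.999)
  thr <- vapply(confs, function(cf) set_positivity_gate(x, cf), numeric(1))
  expect_true(all(diff(thr) >= 0))
})

test_that("at most 1 - confidence of control events exceed their own gate", {
  set.seed(9)
  x <- stats::rlnorm(1e6, log(30), 0.5)
  thr <- set_positivity_gate(x, 0.999)
  expect_gte(mean(x <= thr), 0.999)
  expect_lt(mean(x > thr), 0.0011)
})

test_that("percent positive counts strictly-above events", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  expect_equal(percent_positive(x, 7), 30)
  expect_equal(percent_positive(x, 10), 0)
  expect_equal(percent_positive(x, 0.5), 100)
  expect_true(is.na(percent_positive(numeric(0), 1)))
})

test_that("gating stages are monotone and demultiplexing partitions the live set", {
  sim <- sim_gating_well(debris = 0.05, doublet = 0.04)
  g <- gate_well(sim$events, tiny_gate_config())
  cnt <- g$counts
  expect_true(all(diff(cnt) <= 0))
  expect_equal(sum(vapply(g$populations, nrow, integer(1))),
               unname(cnt["live"]))
  # determinism: same events, same config -> identical thresholds and counts
  g2 <- gate_well(sim$events, tiny_gate_config())
  expect_identical(g$counts, g2$counts)
  expect_identical(g$barcode_threshold, g2$barcode_threshold)
})

test_that("clean synthetic wells recover planted percent positive within 3 SE", {
  cfg <- tiny_config(events_per_well = 30000, seed = 31L)
  gc_ <- tiny_gate_config()
  lay <- cfg$layout
  iso <- lay[lay$reagent_class == "isotype", ][1, ]
  gi <- gate_well(simulate_well(cfg, iso$well, iso$plate, "D1")$events, gc_)
  thr <- lapply(gi$populations, function(e)
    set_positivity_gate(e[, "APC-A"], 0.999))
  truth <- cfg$markers
  for (i in seq_len(nrow(truth))) {
    mrow <- lay[lay$reagent_name == truth$marker[i], ]
    g <- gate_well(simulate_well(cfg, mrow$well, mrow$plate, "D1")$events, gc_)
    for (p in c(1, 2)) {
      pn <- c("PLT", "FCS")[p]
      planted <- c(truth$frac_pop1[i], truth$frac_pop2[i])[p]
      est <- percent_positive(g$populations[[pn]][, "APC-A"], thr[[pn]])
      n <- nrow(g$populations[[pn]])
      tol <- 100 * binom_3se(max(planted, 0.001), n) + 0.15
      expect_lt(abs(est - 100 * planted), tol)
    }
  }
})
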