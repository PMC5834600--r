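test_that("identical config and seed give bit-identical wells", {
  cfg <- tiny_config(events_per_well = 5000)
  w <- first_marker_well(cfg$layout)
  a <- simulate_well(cfg, w$well, w$plate, "D1")
  b <- simulate_well(cfg, w$well, w$plate, "D1")
  expect_identical(a$events, b$events)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth, b$truth)
  # a different seed changes the draw
  c <- simulate_well(cfg, w$well, w$plate, "D1", seed = 999L)
  expect_false(identical(a$events, c$events))
})

test_that("pooling is Bernoulli at ratio/(1+ratio): 1:1 gives ~half per population", {
  cfg <- tiny_config(events_per_well = 50000)
  w <- first_marker_well(cfg$layout)
  sim <- simulate_well(cfg, w$well, w$plate, "D1")
  n1 <- sum(sim$labels$population == "PLT", na.rm = TRUE)
  n <- sum(!is.na(sim$labels$population))
  # binomial oracle: n = 50000, p = 0.5
  expect_lt(abs(n1 - n / 2), 3 * sqrt(n * 0.25))
})

test_that("zero positive fraction gives a pure background log-normal reporter", {
  cfg <- tiny_config(events_per_well = 50000)
  lay <- cfg$layout
  neg_well <- lay[lay$reagent_name == "MK4", ]  # planted 0/0
  sim <- simulate_well(cfg, neg_well$well, neg_well$plate, "D1")
  expect_true(all(!sim$labels$positive))
  # moment agreement: component log-moments within 4 SE of configured values
  for (pn in names(cfg$populations)) {
    pm <- cfg$populations[[pn]]
    x <- log(sim$events[sim$labels$population == pn, "APC-A"])
    nx <- length(x)
    expect_lt(abs(mean(x) - pm$background_logmean),
              4 * pm$background_logsd / sqrt(nx))
    expect_lt(abs(stats::sd(x) - pm$background_logsd),
              4 * pm$background_logsd / sqrt(2 * (nx - 1)))
    xb <- log(sim$events[sim$labels$population == pn, "CTV-A"])
    expect_lt(abs(mean(xb) - pm$barcode_logmean),
              4 * pm$barcode_logsd / sqrt(nx))
  }
})

test_that("default populations encode the scatter and background asymmetry", {
  cfg <- tiny_config(events_per_well = 50000)
  w <- first_marker_well(cfg$layout)
  sim <- simulate_well(cfg, w$well, w$plate, "D1")
  ssc_fcs <- mean(sim$events[sim$labels$population == "FCS", "SSC-A"])
  ssc_plt <- mean(sim$events[sim$labels$population == "PLT", "SSC-A"])
  expect_gt(ssc_fcs, ssc_plt)
  # background on the reporter channel: configured 13x default, negative
  # (non-marker-bound) events only
  neg <- !sim$labels$positive & sim$labels$class == "cell"
  med_fcs <- stats::median(sim$events[neg & sim$labels$population == "FCS",
                                      "APC-A"])
  med_plt <- stats::median(sim$events[neg & sim$labels$population == "PLT",
                                      "APC-A"])
  expect_equal(med_fcs / med_plt, 13, tolerance = 0.1)
})

test_that("event classes conserve the total count", {
  pops <- default_populations(viability_positive_fraction = 0.1)
  cfg <- tiny_config(events_per_well = 10000, debris_fraction = 0.05,
                     doublet_fraction = 0.04, populations = pops)
  w <- first_marker_well(cfg$layout)
  sim <- simulate_well(cfg, w$well, w$plate, "D1")
  lb <- sim$labels
  n_debris <- sum(lb$class == "debris")
  n_doublet <- sum(lb$class == "doublet")
  n_dead <- sum(lb$class == "cell" & lb$dead)
  n_clean <- sum(lb$class == "cell" & !lb$dead)
  expect_identical(n_debris + n_doublet + n_dead + n_clean,
                   cfg$events_per_well)
  tr <- sim$truth
  expect_identical(sum(tr$n_doublet) + tr$n_debris[1] +
                     sum(tr$n_cells), cfg$events_per_well)
  expect_identical(as.integer(sum(tr$n_dead)), n_dead)
})

test_that("zero donor variance replicates planted fractions across donors", {
  cfg <- tiny_config(markers = tiny_truth(donor_logit_sd = 0), n_donors = 3)
  df <- draw_donor_fractions(cfg)
  expect_identical(df$donor_fraction, df$planted_fraction)
  cfg2 <- tiny_config(markers = tiny_truth(donor_logit_sd = 0.3),
                      n_donors = 3)
  df2 <- draw_donor_fractions(cfg2)
  nz <- df2$planted_fraction > 0
  expect_true(any(df2$donor_fraction[nz] != df2$planted_fraction[nz]))
  # fractions stay in [0,1]
  expect_true(all(df2$donor_fraction >= 0 & df2$donor_fraction <= 1))
})

test_that("unknown wells and unlisted markers are rejected", {
  cfg <- tiny_config()
  expect_error(simulate_well(cfg, "H12", "P1", "D1"), "unknown well|empty")
  lay <- tiny_layout(c("MK1", "GHOST"))
  expect_error(plate_sim_config(layout = lay, markers = tiny_truth(),
                                events_per_well = 100),
               "absent from truth list: GHOST")
})

test_that("truth manifest round-trips losslessly", {
  cfg <- tiny_config(events_per_well = 2000, n_donors = 2)
  out <- simulate_screen(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(out$truth, path)
  back <- read_truth(path)
  expect_equal(back, out$truth, ignore_attr = TRUE)
})

test_that("simulate_screen writes FCS files matching its manifest", {
  cfg <- tiny_config(markers = tiny_truth(c("MK1", "MK2"), c(0.5, 0), c(0.2, 0)),
                     layout = tiny_layout(c("MK1", "MK2"), n_iso = 1),
                     events_per_well = 1500, n_donors = 2)
  dir <- withr::local_tempdir()
  out <- simulate_screen(cfg, out_dir = dir)
  man <- read_sample_manifest(file.path(dir, "manifest.tsv"))
  # one file per donor x non-empty well
  expect_equal(nrow(man), 2 * 4)
  expect_true(all(file.exists(file.path(dir, man$file))))
  ev <- read_fcs(file.path(dir, man$file[1]))
  expect_equal(nrow(ev), 1500)
  expect_setequal(colnames(ev),
                  c("FSC-A", "FSC-H", "SSC-A", "CTV-A", "APC-A", "DAPI-A"))
  tr <- read_truth(file.path(dir, "truth.tsv"))
  expect_equal(nrow(tr), nrow(out$truth))
})
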