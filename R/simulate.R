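#' Synthetic list-mode plate simulator
#'
#' Generates per-well flow-cytometry event tables emulating the statistical
#' structure of a pooled two-population antibody-panel screen: two cell
#' populations separated on a barcode-dye channel, a reporter channel whose
#' distribution is a two-component log-normal mixture (autofluorescence
#' background + antibody-positive component), population-specific scatter
#' and background asymmetries, and debris/doublet/dead-cell contamination.
#' Every realized quantity is recorded in a ground-truth manifest so the
#' downstream gating and screening stages can be tested against planted
#' values.
#'
#' @name synthetic-cytometry
NULL

.CHANNELS <- c("FSC-A", "FSC-H", "SSC-A", "CTV-A", "APC-A", "DAPI-A")

#' Describe one cell population for the simulator
#'
#' @param name population label (e.g. "PLT", "FCS")
#' @param scatter_mean length-2 numeric: mean FSC-A and SSC-A (arbitrary
#'   linear units)
#' @param scatter_cov 2x2 symmetric positive-definite covariance of
#'   (FSC-A, SSC-A)
#' @param background_logmean,background_logsd log-normal parameters of the
#'   reporter-channel autofluorescence background
#' @param barcode_logmean,barcode_logsd log-normal parameters of the
#'   barcode-dye channel
#' @param viability_positive_fraction fraction in \[0,1\] of dead
#'   (viability-dye-high) events
#' @return object of class `population_model`
#' @export
population_model <- function(name, scatter_mean, scatter_cov,
                             background_logmean, background_logsd,
                             barcode_logmean, barcode_logsd,
                             viability_positive_fraction = 0) {
  scatter_mean <- as.numeric(scatter_mean)
  scatter_cov <- as.matrix(scatter_cov)
  stopifnot(length(scatter_mean) == 2, all(dim(scatter_cov) == c(2, 2)))
  if (max(abs(scatter_cov - t(scatter_cov))) > 1e-8 ||
      any(eigen(scatter_cov, only.values = TRUE)$values <= 0))
    stop("scatter_cov must be symmetric positive-definite")
  if (background_logsd <= 0 || barcode_logsd <= 0)
    stop("log-scale SDs must be > 0")
  if (viability_positive_fraction < 0 || viability_positive_fraction > 1)
    stop("viability_positive_fraction must be in [0,1]")
  structure(list(
    name = name, scatter_mean = scatter_mean, scatter_cov = scatter_cov,
    background_logmean = background_logmean,
    background_logsd = background_logsd,
    barcode_logmean = barcode_logmean, barcode_logsd = barcode_logsd,
    viability_positive_fraction = viability_positive_fraction
  ), class = "population_model")
}

#' Default two-population models
#'
#' The barcode-labelled population ("PLT") is smaller and less complex; the
#' unlabelled population ("FCS") has higher side scatter and a 13-fold
#' higher median reporter background, the asymmetry the screen's
#' background-corrected statistics must absorb. Barcode modes are separated
#' by ~12.6 log-SDs, i.e. cleanly demultiplexable.
#'
#' @param background_ratio median background ratio FCS/PLT (default 13)
#' @param viability_positive_fraction dead-cell fraction applied to both
#'   populations (default 0: the screening protocol carries no viability
#'   stain)
#' @return named list of two `population_model`s, barcode-positive first
#' @export
default_populations <- function(background_ratio = 13,
                                viability_positive_fraction = 0) {
  cov_plt <- matrix(c(6000^2, 0.3 * 6000 * 5000,
                      0.3 * 6000 * 5000, 5000^2), 2, 2)
  cov_fcs <- matrix(c(7000^2, 0.3 * 7000 * 9000,
                      0.3 * 7000 * 9000, 9000^2), 2, 2)
  list(
    PLT = population_model(
      "PLT", scatter_mean = c(45000, 20000), scatter_cov = cov_plt,
      background_logmean = log(30), background_logsd = 0.5,
      barcode_logmean = log(5000), barcode_logsd = 0.35,
      viability_positive_fraction = viability_positive_fraction),
    FCS = population_model(
      "FCS", scatter_mean = c(55000, 45000), scatter_cov = cov_fcs,
      background_logmean = log(30) + log(background_ratio),
      background_logsd = 0.5,
      barcode_logmean = log(60), barcode_logsd = 0.35,
      viability_positive_fraction = viability_positive_fraction)
  )
}

#' Overlapping-barcode stress preset
#'
#' Moves the labelled population's barcode mode to `sep` log-SDs above the
#' unlabelled mode (equal log-SDs), so demultiplexing operates near the
#' two-component Bayes error boundary.
#'
#' @param populations list of two `population_model`s (labelled first)
#' @param sep separation in log-SD units (default 2)
#' @return modified population list
#' @export
barcode_overlap_preset <- function(populations = default_populations(),
                                   sep = 2) {
  lo <- populations[[2]]
  hi <- populations[[1]]
  hi$barcode_logsd <- lo$barcode_logsd
  hi$barcode_logmean <- lo$barcode_logmean + sep * lo$barcode_logsd
  populations[[1]] <- hi
  populations
}

#' Planted per-marker truth table
#'
#' One row per marker with planted positive fractions per population, the
#' log-intensity shift of the positive component over background, and the
#' donor-level logit-normal SD of the positive fraction.
#'
#' @param marker character vector of marker names
#' @param frac_pop1,frac_pop2 positive fractions in \[0,1\] for the
#'   barcode-positive and barcode-negative populations
#' @param positive_logshift additive log-intensity shift (>= 0) of the
#'   positive over the background component
#' @param donor_logit_sd SD (>= 0) of donor-level logit-normal variation
#' @return data.frame of class `marker_truth`
#' @export
marker_truth <- function(marker, frac_pop1, frac_pop2,
                         positive_logshift = 3, donor_logit_sd = 0.1) {
  df <- data.frame(marker = as.character(marker),
                   frac_pop1 = frac_pop1, frac_pop2 = frac_pop2,
                   positive_logshift = positive_logshift,
                   donor_logit_sd = donor_logit_sd,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$marker)) stop("duplicate marker names in truth")
  if (any(df$frac_pop1 < 0 | df$frac_pop1 > 1 |
          df$frac_pop2 < 0 | df$frac_pop2 > 1))
    stop("positive fractions must be in [0,1]")
  if (any(df$positive_logshift < 0)) stop("positive_logshift must be >= 0")
  if (any(df$donor_logit_sd < 0)) stop("donor_logit_sd must be >= 0")
  class(df) <- c("marker_truth", class(df))
  df
}

#' Default planted truth for the full screening panel
#'
#' Mirrors the structure the screen is designed to resolve: 13 enriched
#' markers (positive fraction 0.5 in the labelled vs 0.2 in the unlabelled
#' population, a planted 2.5-fold increase), 51 markers equally highly
#' expressed in both populations (levels spread over 0.30-0.95), and the
#' remaining 292 panel positions negative in both.
#'
#' @param donor_logit_sd donor-level logit SD for all markers (default 0.1)
#' @return `marker_truth` data.frame with 356 rows
#' @export
default_screen_truth <- function(donor_logit_sd = 0.1) {
  markers <- default_marker_names()
  enriched <- markers[1:13]
  equal <- c(markers[14:26], sprintf("SP-%03d", 1:38))
  frac1 <- stats::setNames(rep(0, length(markers)), markers)
  frac2 <- frac1
  frac1[enriched] <- 0.5
  frac2[enriched] <- 0.2
  lev <- seq(0.30, 0.95, length.out = length(equal))
  frac1[equal] <- lev
  frac2[equal] <- lev
  marker_truth(markers, frac_pop1 = unname(frac1[markers]),
               frac_pop2 = unname(frac2[markers]),
               positive_logshift = 3, donor_logit_sd = donor_logit_sd)
}

#' Configuration of a simulated screening run
#'
#' @param layout `panel_layout` (default [default_panel_layout()])
#' @param populations list of two `population_model`s, barcode-positive
#'   (labelled) population first
#' @param markers `marker_truth` table covering every marker in the layout
#' @param pooling_ratio ratio of population-1 to population-2 events
#'   (default 1, the screen's 1:1 pooling)
#' @param events_per_well events acquired per well (default 50000, the
#'   5e4 cells seeded per well)
#' @param debris_fraction,doublet_fraction contamination fractions
#' @param n_donors number of paired donors (default 3)
#' @param seed integer master seed
#' @return object of class `plate_sim_config`
#' @export
plate_sim_config <- function(layout = default_panel_layout(),
                             populations = default_populations(),
                             markers = default_screen_truth(),
                             pooling_ratio = 1,
                             events_per_well = 50000L,
                             debris_fraction = 0.05,
                             doublet_fraction = 0.04,
                             n_donors = 3L,
                             seed = 1L) {
  validate_layout(layout)
  stopifnot(length(populations) == 2)
  if (events_per_well < 1) stop("events_per_well must be >= 1")
  if (pooling_ratio <= 0) stop("pooling_ratio must be > 0")
  if (debris_fraction < 0 || debris_fraction > 1 ||
      doublet_fraction < 0 || doublet_fraction > 1)
    stop("contamination fractions must be in [0,1]")
  if (n_donors < 1) stop("n_donors must be >= 1")
  marker_wells <- layout$reagent_name[layout$reagent_class == "marker"]
  absent <- setdiff(marker_wells, markers$marker)
  if (length(absent) > 0)
    stop("marker(s) referenced by layout absent from truth list: ",
         paste(utils::head(absent, 5), collapse = ", "),
         if (length(absent) > 5) ", ...")
  structure(list(
    layout = layout, populations = populations, markers = markers,
    pooling_ratio = pooling_ratio,
    events_per_well = as.integer(events_per_well),
    debris_fraction = debris_fraction, doublet_fraction = doublet_fraction,
    n_donors = as.integer(n_donors), seed = as.integer(seed)
  ), class = "plate_sim_config")
}

# deterministic per-well seed derivation, kept below 2^31 (exact in doubles)
.derive_seed <- function(seed, donor_i, plate_i, well_i) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  as.integer((s * 48271 + donor_i * 1299709 + plate_i * 15485863 +
                well_i * 104729 + 1) %% m)
}

#' Draw donor-level positive fractions
#'
#' Per donor, marker and population the planted fraction is perturbed on
#' the logit scale: `plogis(qlogis(f) + N(0, donor_logit_sd))`. Fractions
#' of exactly 0 or 1 are left untouched. Deterministic given the config's
#' seed.
#'
#' @param config `plate_sim_config`
#' @return data.frame: donor, marker, population, planted_fraction,
#'   donor_fraction
#' @export
draw_donor_fractions <- function(config) {
  set.seed(.derive_seed(config$seed, 0, 0, 0))
  tr <- config$markers
  pops <- names(config$populations)
  out <- vector("list", config$n_donors * 2L)
  k <- 0L
  for (d in seq_len(config$n_donors)) {
    for (p in 1:2) {
      f <- if (p == 1) tr$frac_pop1 else tr$frac_pop2
      eps <- stats::rnorm(nrow(tr), 0, tr$donor_logit_sd)
      fd <- ifelse(f <= 0 | f >= 1 | tr$donor_logit_sd == 0, f,
                   stats::plogis(stats::qlogis(f) + eps))
      k <- k + 1L
      out[[k]] <- data.frame(
        donor = paste0("D", d), marker = tr$marker, population = pops[p],
        planted_fraction = f, donor_fraction = fd, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

.well_fractions <- function(config, reagent, reagent_class, donor,
                            donor_fractions) {
  pops <- names(config$populations)
  if (reagent_class != "marker")
    return(stats::setNames(c(0, 0), pops))
  sel <- donor_fractions$donor == donor & donor_fractions$marker == reagent
  f <- donor_fractions[sel, ]
  stats::setNames(f$donor_fraction[match(pops, f$population)], pops)
}

#' Simulate one well of a pooled two-population plate
#'
#' Events are drawn as: class (debris / doublet / cell) from the configured
#' contamination fractions; population label Bernoulli with probability
#' `pooling_ratio / (1 + pooling_ratio)`; scatter bivariate normal per
#' population with FSC-H proportional to FSC-A plus log-normal noise;
#' barcode and reporter log-normal per population, the reporter a
#' two-component mixture at the well's donor-level positive fraction
#' (isotype/unstained wells are pure background); doublets carry doubled
#' areas, 1.2x height and doubled dye content; debris has small scatter;
#' dead cells are viability-dye-high. Rows are randomly permuted. Identical
#' `(config, seed)` gives bit-identical output.
#'
#' @param config `plate_sim_config`
#' @param well well coordinate, e.g. "B7"
#' @param plate plate id as in the layout (default first plate)
#' @param donor donor id, e.g. "D1"
#' @param seed integer seed for this well; derived from the config seed and
#'   indices when `NULL`
#' @param donor_fractions output of [draw_donor_fractions()]; recomputed
#'   when `NULL`
#' @return list with `events` (numeric matrix, channels FSC-A, FSC-H,
#'   SSC-A, CTV-A, APC-A, DAPI-A),
#'   `labels` (per-event data.frame: class, population, dead, positive) and
#'   `truth` (per-population summary data.frame)
#' @export
simulate_well <- function(config, well, plate = NULL, donor = "D1",
                          seed = NULL, donor_fractions = NULL) {
  lay <- config$layout
  if (is.null(plate)) plate <- lay$plate[1]
  row <- lay[lay$plate == plate & lay$well == well, ]
  if (nrow(row) != 1)
    stop("unknown well ", plate, ":", well, " in layout")
  if (row$reagent_class == "empty")
    stop("well ", plate, ":", well, " is empty; nothing to simulate")
  if (is.null(donor_fractions)) donor_fractions <- draw_donor_fractions(config)
  donor_i <- as.integer(sub("^D", "", donor))
  if (is.na(donor_i)) donor_i <- 0L
  plate_i <- match(plate, unique(lay$plate))
  well_i <- match(well, well_grid())
  if (is.null(seed))
    seed <- .derive_seed(config$seed, donor_i, plate_i, well_i)
  fracs <- .well_fractions(config, row$reagent_name, row$reagent_class,
                           donor, donor_fractions)

  set.seed(seed)
  n <- config$events_per_well
  pops <- config$populations
  pop_names <- names(pops)
  p1 <- config$pooling_ratio / (1 + config$pooling_ratio)

  cls <- sample(c("debris", "doublet", "cell"), n, replace = TRUE,
                prob = c(config$debris_fraction, config$doublet_fraction,
                         1 - config$debris_fraction - config$doublet_fraction))
  is_cellish <- cls != "debris"
  pop <- rep(NA_character_, n)
  pop[is_cellish] <- pop_names[2L - (stats::runif(sum(is_cellish)) < p1)]
  dead <- rep(FALSE, n)
  positive <- rep(FALSE, n)

  fsc_a <- fsc_h <- ssc_a <- ctv <- apc <- dapi <- numeric(n)

  mean_fsc <- mean(vapply(pops, function(p) p$scatter_mean[1], numeric(1)))
  min_bc_log <- min(vapply(pops, function(p) p$barcode_logmean, numeric(1)))
  min_bg_log <- min(vapply(pops, function(p) p$background_logmean, numeric(1)))

  for (pn in pop_names) {
    pm <- pops[[pn]]
    idx <- which(pop == pn)
    if (length(idx) == 0) next
    np <- length(idx)
    sc <- MASS::mvrnorm(np, mu = pm$scatter_mean, Sigma = pm$scatter_cov)
    sc <- pmax(sc, 1)
    fa <- sc[, 1]
    fh <- fa * 0.95 * exp(stats::rnorm(np, 0, 0.03))
    sa <- sc[, 2]
    bc <- stats::rlnorm(np, pm$barcode_logmean, pm$barcode_logsd)
    f <- fracs[[pn]]
    is_pos <- stats::runif(np) < f
    rp <- stats::rlnorm(np, pm$background_logmean +
                          as.numeric(is_pos) *
                          .marker_logshift(config, row),
                        pm$background_logsd)
    is_dead <- cls[idx] == "cell" &
      stats::runif(np) < pm$viability_positive_fraction
    vd <- stats::rlnorm(np, log(100), 0.4)
    if (any(is_dead))
      vd[is_dead] <- stats::rlnorm(sum(is_dead), log(5000), 0.4)
    # doublets: two cells in one droplet -- areas and dye content double,
    # pulse height rises sub-proportionally
    dbl <- cls[idx] == "doublet"
    fa[dbl] <- fa[dbl] * 2
    fh[dbl] <- fh[dbl] * 1.2
    sa[dbl] <- sa[dbl] * 2
    bc[dbl] <- bc[dbl] * 2
    rp[dbl] <- rp[dbl] * 2
    fsc_a[idx] <- fa; fsc_h[idx] <- fh; ssc_a[idx] <- sa
    ctv[idx] <- bc; apc[idx] <- rp; dapi[idx] <- vd
    dead[idx] <- is_dead
    positive[idx] <- is_pos
  }
  deb <- which(cls == "debris")
  if (length(deb) > 0) {
    nd <- length(deb)
    fa <- stats::rlnorm(nd, log(0.15 * mean_fsc), 0.3)
    fsc_a[deb] <- fa
    fsc_h[deb] <- fa * 0.95 * exp(stats::rnorm(nd, 0, 0.05))
    ssc_a[deb] <- stats::rlnorm(nd, log(0.1 * mean_fsc), 0.4)
    ctv[deb] <- stats::rlnorm(nd, min_bc_log - 1, 0.5)
    apc[deb] <- stats::rlnorm(nd, min_bg_log - 1, 0.5)
    dapi[deb] <- stats::rlnorm(nd, log(100), 0.4)
  }

  perm <- sample.int(n)
  events <- cbind(`FSC-A` = fsc_a, `FSC-H` = fsc_h, `SSC-A` = ssc_a,
                  `CTV-A` = ctv, `APC-A` = apc, `DAPI-A` = dapi)[perm, ,
                                                                 drop = FALSE]
  labels <- data.frame(class = cls, population = pop, dead = dead,
                       positive = positive, stringsAsFactors = FALSE)[perm, ]
  rownames(labels) <- NULL

  summ <- do.call(rbind, lapply(pop_names, function(pn) {
    cell <- labels$class == "cell" & labels$population == pn
    dblp <- labels$class == "doublet" & labels$population == pn
    n_cells <- sum(cell)
    data.frame(
      donor = donor, plate = plate, well = well,
      reagent = row$reagent_name, reagent_class = row$reagent_class,
      population = pn,
      n_total = n, n_debris = sum(labels$class == "debris"),
      n_doublet = sum(dblp), n_cells = n_cells,
      n_dead = sum(cell & labels$dead),
      n_positive = sum(cell & labels$positive),
      planted_fraction = unname(fracs[[pn]]),
      realized_fraction = if (n_cells > 0)
        sum(cell & labels$positive) / n_cells else NA_real_,
      seed = seed, stringsAsFactors = FALSE)
  }))
  list(events = events, labels = labels, truth = summ)
}

.marker_logshift <- function(config, layout_row) {
  if (layout_row$reagent_class != "marker") return(0)
  config$markers$positive_logshift[
    match(layout_row$reagent_name, config$markers$marker)]
}

#' Simulate a full screen and optionally write it to disk
#'
#' Iterates donors x plates x non-empty wells. With `out_dir` set, one FCS
#' 3.1 file per well is written together with a sample manifest
#' (`manifest.tsv`) and the ground-truth manifest (`truth.tsv`); only the
#' truth is kept in memory. With `out_dir = NULL` all event tables are
#' returned, which is only sensible for small configurations.
#'
#' @param config `plate_sim_config`
#' @param out_dir output directory or `NULL`
#' @return list with `truth` (per well x population data.frame),
#'   `manifest` (when writing), and `wells` (named list of
#'   events/labels, when `out_dir` is `NULL`)
#' @export
simulate_screen <- function(config, out_dir = NULL) {
  if (config$n_donors < 1) stop("n_donors must be >= 1")
  donor_fractions <- draw_donor_fractions(config)
  lay <- config$layout[config$layout$reagent_class != "empty", ]
  write_files <- !is.null(out_dir)
  if (write_files) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- vector("list", config$n_donors * nrow(lay))
  manifest <- if (write_files) truth else NULL
  wells <- if (!write_files) list() else NULL
  k <- 0L
  for (d in seq_len(config$n_donors)) {
    donor <- paste0("D", d)
    for (i in seq_len(nrow(lay))) {
      k <- k + 1L
      sim <- simulate_well(config, lay$well[i], lay$plate[i], donor,
                           donor_fractions = donor_fractions)
      truth[[k]] <- sim$truth
      if (write_files) {
        fname <- sprintf("%s_%s_%s.fcs", donor, lay$plate[i], lay$well[i])
        write_fcs(sim$events, file.path(out_dir, fname),
                  extra_keywords = c(PLATE = lay$plate[i], WELL = lay$well[i],
                                     DONOR = donor))
        manifest[[k]] <- data.frame(
          file = fname, donor = donor, condition = "pooled",
          plate = lay$plate[i], well = lay$well[i], stringsAsFactors = FALSE)
      } else {
        wells[[sprintf("%s_%s_%s", donor, lay$plate[i], lay$well[i])]] <-
          sim[c("events", "labels")]
      }
    }
  }
  truth <- do.call(rbind, truth)
  out <- list(truth = truth)
  if (write_files) {
    out$manifest <- do.call(rbind, manifest)
    utils::write.table(out$manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_truth(truth, file.path(out_dir, "truth.tsv"))
  } else {
    out$wells <- wells
  }
  out
}

#' Write / read the ground-truth manifest
#'
#' Plain TSV serialization of the per-well, per-population truth table;
#' numeric columns round-trip losslessly at double precision read-back.
#'
#' @param truth truth data.frame as returned by [simulate_screen()]
#' @param path file path
#' @return `read_truth` returns the data.frame
#' @export
write_truth <- function(truth, path) {
  df <- truth
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read a sample manifest (file, donor, condition, plate, well)
#' @param path TSV path
#' @return data.frame
#' @export
read_sample_manifest <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  req <- c("file", "donor", "condition", "plate", "well")
  if (!all(req %in% names(m)))
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(m$file)) stop("duplicate file paths in manifest")
  m
}
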