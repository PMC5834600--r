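#' Event-level gating
#'
#' Stage chain for one well: acquisition QC, scatter (debris) gate, doublet
#' exclusion on FSC-H vs FSC-A, optional viability gate against a control,
#' barcode demultiplexing into the two pooled populations, and
#' control-referenced positivity gating on the reporter channel.
#'
#' @name gating
NULL

.default_channel_map <- function() {
  c(scatter_area = "FSC-A", scatter_height = "FSC-H", ssc = "SSC-A",
    barcode = "CTV-A", reporter = "APC-A", viability = "DAPI-A")
}

#' Gating configuration
#'
#' @param min_events_per_well acquisition QC floor (default 10000 events)
#' @param scatter_gate list: `method` one of "mode-anchor" (threshold =
#'   main FSC-A density mode minus `k` robust SDs of the central mass),
#'   "fixed" (explicit `threshold`), or "none"
#' @param doublet_band half-width, in robust SDs of the central-mass
#'   log(FSC-H/FSC-A) ratio, of the singlet band (default 5)
#' @param viability_quantile control quantile defining the dead-cell
#'   threshold (default 0.999)
#' @param barcode_method "kde-valley" (default), "otsu" or "fixed"
#' @param barcode_threshold linear threshold used when
#'   `barcode_method = "fixed"`
#' @param valley_prominence minimum KDE valley prominence, as a fraction of
#'   the tallest peak (default 0.05)
#' @param kurtosis_max when no qualifying KDE valley exists, log-barcode
#'   sample kurtosis at or above this value judges the distribution
#'   unimodal (error); below it, the variance-maximizing fallback split is
#'   used (default 2.9; an equal two-component mixture at 2 SD separation
#'   has kurtosis 2.5, one component alone 3.0)
#' @param positivity_confidence isotype/unstained-control confidence for
#'   the positivity gate (default 0.999)
#' @param channels named map from logical roles (scatter_area,
#'   scatter_height, ssc, barcode, reporter, viability) to physical channel
#'   names; set `viability` to `NA` to skip the live gate (screening mode)
#' @param population_labels names given to the barcode-negative and
#'   barcode-positive populations
#' @return object of class `gate_config`
#' @export
gate_config <- function(min_events_per_well = 10000L,
                        scatter_gate = list(method = "mode-anchor", k = 3),
                        doublet_band = 5,
                        viability_quantile = 0.999,
                        barcode_method = c("kde-valley", "otsu", "fixed"),
                        barcode_threshold = NULL,
                        valley_prominence = 0.05,
                        kurtosis_max = 2.9,
                        positivity_confidence = 0.999,
                        channels = .default_channel_map(),
                        population_labels = c(negative = "FCS",
                                              positive = "PLT")) {
  barcode_method <- match.arg(barcode_method)
  if (min_events_per_well < 1) stop("min_events_per_well must be >= 1")
  if (positivity_confidence <= 0 || positivity_confidence >= 1)
    stop("positivity_confidence must be in (0,1)")
  if (viability_quantile <= 0 || viability_quantile > 1)
    stop("viability_quantile must be in (0,1]")
  if (barcode_method == "fixed" && is.null(barcode_threshold))
    stop("barcode_method 'fixed' requires barcode_threshold")
  structure(list(
    min_events_per_well = as.integer(min_events_per_well),
    scatter_gate = scatter_gate, doublet_band = doublet_band,
    viability_quantile = viability_quantile,
    barcode_method = barcode_method, barcode_threshold = barcode_threshold,
    valley_prominence = valley_prominence, kurtosis_max = kurtosis_max,
    positivity_confidence = positivity_confidence,
    channels = channels, population_labels = population_labels
  ), class = "gate_config")
}

.chan <- function(events, config, role) {
  name <- config$channels[[role]]
  if (is.na(name)) stop("channel role '", role, "' is unbound")
  if (!name %in% colnames(events))
    stop("channel-mapping error: channel '", name, "' (role ", role,
         ") absent from event table")
  events[, name]
}

.keep <- function(events, idx) {
  out <- events[idx, , drop = FALSE]
  attr(out, "kept") <- idx
  out
}

#' Acquisition quality control for one well
#'
#' @param events event matrix
#' @param config `gate_config`
#' @return list with `pass` (logical) and `reason` (string)
#' @export
qc_well <- function(events, config = gate_config()) {
  n <- nrow(events)
  if (n == 0)
    return(list(pass = FALSE, reason = "empty well (0 events)"))
  if (n < config$min_events_per_well)
    return(list(pass = FALSE,
                reason = sprintf("only %d events acquired (minimum %d)",
                                 n, config$min_events_per_well)))
  list(pass = TRUE, reason = "ok")
}

#' Scatter gate: remove the low-FSC debris cluster
#'
#' Default method anchors the threshold at the main mode of the FSC-A
#' kernel density and subtracts `k` robust SDs of the central mass (events
#' above 40% of the mode); events below the threshold are removed.
#'
#' @param events event matrix
#' @param config `gate_config`
#' @return retained subset with attributes `kept` (row indices),
#'   `threshold` and `retained_fraction`
#' @export
gate_cells <- function(events, config = gate_config()) {
  sg <- config$scatter_gate
  fsc <- .chan(events, config, "scatter_area")
  if (identical(sg$method, "none"))
    return(.keep(events, seq_len(nrow(events))))
  thr <- if (identical(sg$method, "fixed")) {
    sg$threshold
  } else {
    d <- stats::density(fsc)
    m <- d$x[which.max(d$y)]
    core <- fsc[fsc > 0.4 * m]
    k <- if (is.null(sg$k)) 3 else sg$k
    m - k * stats::mad(core, center = m)
  }
  idx <- which(fsc >= thr)
  if (length(idx) == 0)
    warning("empty gate: scatter gate removed all events")
  out <- .keep(events, idx)
  attr(out, "threshold") <- thr
  attr(out, "retained_fraction") <- length(idx) / nrow(events)
  out
}

#' Doublet exclusion on the FSC-H vs FSC-A relation
#'
#' Fits the singlet line robustly as the median log(FSC-H/FSC-A) ratio of
#' the central mass (FSC-A between its 10% and 90% quantiles) and removes
#' events whose log-ratio residual falls outside `doublet_band` robust SDs.
#' Doublets carry roughly doubled area at sub-proportional height, so they
#' sit far below the band.
#'
#' @param events event matrix
#' @param config `gate_config`
#' @return retained subset with attributes `kept` and `removed_fraction`
#' @export
exclude_doublets <- function(events, config = gate_config()) {
  n <- nrow(events)
  if (n < 50) {
    warning("fewer than 50 events; doublet fit unstable, stage skipped")
    return(.keep(events, seq_len(n)))
  }
  fa <- .chan(events, config, "scatter_area")
  fh <- .chan(events, config, "scatter_height")
  lr <- log(pmax(fh, .Machine$double.eps) / pmax(fa, .Machine$double.eps))
  qs <- stats::quantile(fa, c(0.1, 0.9), type = 7)
  central <- lr[fa >= qs[1] & fa <= qs[2]]
  r0 <- stats::median(central)
  s <- stats::mad(central)
  idx <- which(abs(lr - r0) <= config$doublet_band * s)
  out <- .keep(events, idx)
  attr(out, "removed_fraction") <- 1 - length(idx) / n
  out
}

#' Viability gate against a dead-cell-dye control
#'
#' The threshold is the configured quantile (type-7) of the control's
#' viability channel; sample events strictly above it are removed.
#'
#' @param events event matrix
#' @param viability_control event matrix of the control used to place the
#'   threshold
#' @param config `gate_config`
#' @return retained subset with attributes `kept`, `threshold` and
#'   `removed_fraction`
#' @export
exclude_dead <- function(events, viability_control, config = gate_config()) {
  ctrl <- .chan(viability_control, config, "viability")
  x <- .chan(events, config, "viability")
  thr <- unname(stats::quantile(ctrl, config$viability_quantile, type = 7))
  idx <- which(x <= thr)
  out <- .keep(events, idx)
  attr(out, "threshold") <- thr
  attr(out, "removed_fraction") <- 1 - length(idx) / nrow(events)
  out
}

.otsu_split <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs)
  tot <- cs[n]
  k <- seq_len(n - 1)
  w1 <- k / n
  w2 <- 1 - w1
  m1 <- cs[k] / k
  m2 <- (tot - cs[k]) / (n - k)
  bv <- w1 * w2 * (m1 - m2)^2
  kbest <- which.max(bv)
  (xs[kbest] + xs[kbest + 1]) / 2
}

.kurtosis <- function(x) {
  z <- x - mean(x)
  n <- length(z)
  (sum(z^4) / n) / (sum(z^2) / n)^2
}

#' Demultiplex pooled populations on the barcode channel
#'
#' Default method: kernel-density estimate (Silverman's bandwidth) of the
#' log barcode intensity; the threshold sits at the minimum-density valley
#' between the two largest modes, provided the valley prominence reaches
#' `valley_prominence` of the tallest peak. When no qualifying valley
#' exists, the log-barcode kurtosis arbitrates: a flattened (platykurtic)
#' shape indicates an overlapping two-component mixture and falls back to
#' the variance-maximizing (Otsu) split; otherwise the distribution is
#' judged unimodal and demultiplexing fails for the well.
#'
#' @param events event matrix
#' @param config `gate_config`
#' @return list with `negative` and `positive` event subsets (each with a
#'   `kept` attribute), and the linear `threshold`
#' @export
demultiplex_barcode <- function(events, config = gate_config()) {
  bc <- .chan(events, config, "barcode")
  x <- log(pmax(bc, .Machine$double.eps))
  thr_log <- switch(
    config$barcode_method,
    fixed = log(config$barcode_threshold),
    otsu = .otsu_split(x),
    "kde-valley" = {
      d <- stats::density(x)
      y <- d$y
      np <- length(y)
      is_peak <- c(FALSE, y[2:(np - 1)] > y[1:(np - 2)] &
                     y[2:(np - 1)] >= y[3:np], FALSE)
      peaks <- which(is_peak)
      valley_thr <- NA_real_
      if (length(peaks) >= 2) {
        top2 <- peaks[order(y[peaks], decreasing = TRUE)[1:2]]
        lo <- min(top2); hi <- max(top2)
        vi <- lo + which.min(y[(lo + 1):(hi - 1)])
        prominence <- min(y[top2]) - y[vi]
        if (prominence >= config$valley_prominence * max(y))
          valley_thr <- d$x[vi]
      }
      if (!is.na(valley_thr)) {
        valley_thr
      } else if (.kurtosis(x) < config$kurtosis_max) {
        .otsu_split(x)
      } else {
        stop("demultiplexing error: barcode distribution judged unimodal")
      }
    }
  )
  pos_idx <- which(x > thr_log)
  neg_idx <- which(x <= thr_log)
  list(negative = .keep(events, neg_idx),
       positive = .keep(events, pos_idx),
       threshold = exp(thr_log))
}

#' Positivity gate from a negative control
#'
#' The gate is the empirical `confidence` quantile (type-7, linearly
#' interpolated order statistics) of the control's reporter channel, so by
#' construction at most `1 - confidence` of control events exceed it.
#'
#' @param control_events control event matrix, or a numeric vector of
#'   reporter intensities
#' @param confidence gate confidence in (0,1), default 0.999
#' @param config `gate_config` (channel map)
#' @param min_control_events minimum control size (default 100)
#' @return numeric threshold
#' @export
set_positivity_gate <- function(control_events,
                                confidence = 0.999,
                                config = gate_config(),
                                min_control_events = 100L) {
  x <- if (is.matrix(control_events) || is.data.frame(control_events))
    .chan(as.matrix(control_events), config, "reporter")
  else as.numeric(control_events)
  if (length(x) < min_control_events)
    stop("gate error: control has ", length(x),
         " events (minimum ", min_control_events, ")")
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0,1)")
  unname(stats::quantile(x, confidence, type = 7))
}

#' Percent of events above a positivity gate
#'
#' Events strictly above the threshold count as positive (ties are
#' negative). Returns `NA` for an empty input rather than raising.
#'
#' @param events event matrix or numeric reporter vector
#' @param threshold positivity gate
#' @param config `gate_config` (channel map)
#' @return percentage on the 0-100 scale, or `NA_real_` when undefined
#' @export
percent_positive <- function(events, threshold, config = gate_config()) {
  x <- if (is.matrix(events) || is.data.frame(events))
    .chan(as.matrix(events), config, "reporter")
  else as.numeric(events)
  if (length(x) == 0) return(NA_real_)
  100 * sum(x > threshold) / length(x)
}

#' Run the full gating chain on one well
#'
#' total -> non-debris -> singlet -> live (skipped when the viability role
#' is unbound or no control is given) -> demultiplexed populations.
#'
#' @param events event matrix
#' @param config `gate_config`
#' @param viability_control optional control event matrix for the live gate
#' @return list: `qc`, `counts` (named stage counts), `populations` (named
#'   list of event subsets keyed by `population_labels`), `barcode_threshold`
#' @export
gate_well <- function(events, config = gate_config(),
                      viability_control = NULL) {
  qc <- qc_well(events, config)
  nondebris <- gate_cells(events, config)
  singlet <- exclude_doublets(nondebris, config)
  live <- if (!is.null(viability_control) &&
              !is.na(config$channels[["viability"]])) {
    exclude_dead(singlet, viability_control, config)
  } else singlet
  dm <- demultiplex_barcode(live, config)
  pops <- stats::setNames(list(dm$negative, dm$positive),
                          config$population_labels[c("negative", "positive")])
  counts <- c(total = nrow(events), nondebris = nrow(nondebris),
              singlet = nrow(singlet), live = nrow(live))
  list(qc = qc, counts = counts, populations = pops,
       barcode_threshold = dm$threshold)
}
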