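#' Whole-screen pipeline
#'
#' Streams donor x plate x well event tables (simulated in memory, or read
#' back from FCS files) through the gating chain, collects per-well,
#' per-population statistics referenced to each plate's matched isotype
#' controls, and aggregates them into the marker-level screen result.
#'
#' @name pipeline
NULL

.pop_reporter <- function(gated, config) {
  lapply(gated$populations, function(ev)
    if (nrow(ev) > 0) .chan(ev, config, "reporter") else numeric(0))
}

#' Event source reading wells back from simulated FCS files
#'
#' @param manifest sample manifest data.frame (see [read_sample_manifest()])
#' @param dir directory holding the FCS files
#' @return function(donor, plate, well) -> event matrix
#' @export
fcs_well_source <- function(manifest, dir) {
  function(donor, plate, well) {
    sel <- manifest$donor == donor & manifest$plate == plate &
      manifest$well == well
    if (sum(sel) != 1)
      stop("manifest resolves ", sum(sel), " files for ",
           donor, " ", plate, ":", well)
    read_fcs(file.path(dir, manifest$file[sel]))
  }
}

#' Run the gating stage over a whole screen
#'
#' For every donor and plate the isotype and unstained control wells are
#' gated first; per-population positivity gates are placed on each isotype
#' control at the configured confidence. Marker wells are then gated and
#' quantified against the matched isotype gate of their `isotype_group`:
#' percent positive, median reporter intensity of all and of positive
#' events, and stain index against the matched control. Background
#' statistics pool the control wells per population.
#'
#' @param config `plate_sim_config` describing the screen (layout, donors;
#'   and, when simulating, the generative truth)
#' @param gate_cfg `gate_config`
#' @param well_source `NULL` to simulate wells in memory from `config`, or
#'   a function(donor, plate, well) returning an event matrix (see
#'   [fcs_well_source()])
#' @return list of class `screen_run`: `well_stats` (per well x population
#'   data.frame), `background` (per-population background table with ratio
#'   attribute), `truth` (planted truth when simulating), `failed_wells`
#' @export
run_screen <- function(config, gate_cfg = gate_config(),
                       well_source = NULL) {
  lay <- config$layout[config$layout$reagent_class != "empty", ]
  simulate <- is.null(well_source)
  donor_fractions <- if (simulate) draw_donor_fractions(config) else NULL
  pops <- gate_cfg$population_labels[c("negative", "positive")]
  truth_rows <- list()
  stats_rows <- list()
  failed <- list()
  ctrl_pool <- stats::setNames(list(numeric(0), numeric(0)), pops)

  for (d in seq_len(config$n_donors)) {
    donor <- paste0("D", d)
    for (plate in unique(lay$plate)) {
      pl <- lay[lay$plate == plate, ]
      # control wells first: they carry the gates for this plate
      pl <- pl[order(pl$reagent_class != "isotype",
                     pl$reagent_class != "unstained"), ]
      iso_gates <- list()    # [[isotype_group]][[population]] -> threshold
      iso_ctrl <- list()     # [[isotype_group]][[population]] -> reporter
      for (i in seq_len(nrow(pl))) {
        well <- pl$well[i]
        rclass <- pl$reagent_class[i]
        events <- if (simulate) {
          sim <- simulate_well(config, well, plate, donor,
                               donor_fractions = donor_fractions)
          truth_rows[[length(truth_rows) + 1L]] <- sim$truth
          sim$events
        } else {
          well_source(donor, plate, well)
        }
        gated <- tryCatch(gate_well(events, gate_cfg),
                          error = function(e) e)
        if (inherits(gated, "error") || !gated$qc$pass) {
          reason <- if (inherits(gated, "error"))
            conditionMessage(gated) else gated$qc$reason
          failed[[length(failed) + 1L]] <- data.frame(
            donor = donor, plate = plate, well = well,
            reagent = pl$reagent_name[i], reason = reason,
            stringsAsFactors = FALSE)
          next
        }
        rep_by_pop <- .pop_reporter(gated, gate_cfg)
        if (rclass %in% c("isotype", "unstained")) {
          for (pn in pops)
            ctrl_pool[[pn]] <- c(ctrl_pool[[pn]], rep_by_pop[[pn]])
        }
        if (rclass == "isotype") {
          grp <- pl$isotype_group[i]
          iso_ctrl[[grp]] <- rep_by_pop
          iso_gates[[grp]] <- lapply(rep_by_pop, function(x)
            set_positivity_gate(x, gate_cfg$positivity_confidence,
                                gate_cfg))
        }
        thr_by_pop <- ctrl_by_pop <- NULL
        if (rclass == "marker") {
          grp <- pl$isotype_group[i]
          if (is.null(iso_gates[[grp]]))
            stop("isotype group '", grp, "' has no gated control on plate ",
                 plate, " (donor ", donor, ")")
          thr_by_pop <- iso_gates[[grp]]
          ctrl_by_pop <- iso_ctrl[[grp]]
        }
        for (pn in pops) {
          x <- rep_by_pop[[pn]]
          thr <- if (!is.null(thr_by_pop)) thr_by_pop[[pn]] else NA_real_
          pos <- if (!is.na(thr)) x[x > thr] else numeric(0)
          stats_rows[[length(stats_rows) + 1L]] <- data.frame(
            donor = donor, plate = plate, well = well,
            reagent = pl$reagent_name[i], reagent_class = rclass,
            isotype_group = pl$isotype_group[i], population = pn,
            n_total = unname(gated$counts["total"]),
            n_nondebris = unname(gated$counts["nondebris"]),
            n_singlet = unname(gated$counts["singlet"]),
            n_live = unname(gated$counts["live"]),
            n_pop = length(x),
            barcode_threshold = gated$barcode_threshold,
            positivity_threshold = thr,
            pct_positive = if (!is.na(thr))
              percent_positive(x, thr, gate_cfg) else NA_real_,
            mfi_all = if (length(x) > 0) stats::median(x) else NA_real_,
            mfi_pos = if (length(pos) > 0) stats::median(pos) else NA_real_,
            stain_index = if (!is.null(ctrl_by_pop))
              stain_index(x, ctrl_by_pop[[pn]], gate_cfg) else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- list(
    well_stats = do.call(rbind, stats_rows),
    background = background_stats(ctrl_pool),
    failed_wells = if (length(failed) > 0) do.call(rbind, failed) else NULL,
    populations = unname(pops)
  )
  if (simulate) out$truth <- do.call(rbind, truth_rows)
  class(out) <- "screen_run"
  out
}

#' Aggregate well statistics into the marker-level screen result
#'
#' Per marker: donor-mean percent positive per population, fold increase of
#' the labelled over the reference population (floored denominator), a
#' significance test across donors, and the classification flags. The flag
#' hierarchy is enforced: `enriched` implies `variable` implies `positive`.
#'
#' @param run `screen_run` from [run_screen()], or its `well_stats`
#'   data.frame
#' @param screen_cfg `screen_config`
#' @param populations character(2): reference population first, labelled
#'   (numerator) population second; defaults to the run's populations
#' @return list of class `screen_result`: `markers` (one row per marker),
#'   `percent_positive` (marker x donor x population long table),
#'   `stain_index` (long table), `background`
#' @export
screen_markers <- function(run, screen_cfg = screen_config(),
                           populations = NULL) {
  ws <- if (inherits(run, "screen_run")) run$well_stats else run
  if (is.null(populations))
    populations <- if (inherits(run, "screen_run")) run$populations
  else c("FCS", "PLT")
  ref_pop <- populations[1]
  num_pop <- populations[2]
  mk <- ws[ws$reagent_class == "marker", ]
  markers <- unique(mk$reagent)
  n_markers <- length(markers)

  pct_long <- mk[, c("reagent", "donor", "population", "pct_positive")]
  names(pct_long)[1] <- "marker"
  si_long <- mk[, c("reagent", "donor", "population", "stain_index")]
  names(si_long)[1] <- "marker"

  rows <- vector("list", n_markers)
  for (i in seq_len(n_markers)) {
    m <- markers[i]
    sub <- mk[mk$reagent == m, ]
    p_num <- sub$pct_positive[sub$population == num_pop]
    p_ref <- sub$pct_positive[sub$population == ref_pop]
    si_num <- sub$stain_index[sub$population == num_pop]
    si_ref <- sub$stain_index[sub$population == ref_pop]
    mean_num <- mean(p_num, na.rm = TRUE)
    mean_ref <- mean(p_ref, na.rm = TRUE)
    fold <- fold_increase(mean_num, mean_ref, screen_cfg$fold_floor_pct)
    pval <- if (sum(!is.na(p_num)) >= 2 && sum(!is.na(p_ref)) >= 2)
      test_marker(p_num[!is.na(p_num)], p_ref[!is.na(p_ref)], screen_cfg)
    else NA_real_
    msi_num <- mean(si_num, na.rm = TRUE)
    msi_ref <- mean(si_ref, na.rm = TRUE)
    rows[[i]] <- data.frame(
      marker = m,
      pct_plt = mean_num, pct_fcs = mean_ref,
      sem_plt = stats::sd(p_num) / sqrt(sum(!is.na(p_num))),
      sem_fcs = stats::sd(p_ref) / sqrt(sum(!is.na(p_ref))),
      fold = as.numeric(fold), fold_floored = attr(fold, "floored"),
      p_value = pval,
      si_plt = msi_num, si_fcs = msi_ref,
      si_fold = si_fold(msi_num, msi_ref),
      stringsAsFactors = FALSE)
  }
  tab <- if (n_markers > 0) do.call(rbind, rows) else data.frame(
    marker = character(0), pct_plt = numeric(0), pct_fcs = numeric(0),
    sem_plt = numeric(0), sem_fcs = numeric(0), fold = numeric(0),
    fold_floored = logical(0), p_value = numeric(0), si_plt = numeric(0),
    si_fcs = numeric(0), si_fold = numeric(0), stringsAsFactors = FALSE)
  tab$p_adj <- if (screen_cfg$multiplicity == "benjamini-hochberg")
    stats::p.adjust(tab$p_value, method = "BH") else tab$p_value
  p_used <- tab$p_adj
  tab$positive <- classify_positive(tab$pct_plt, tab$pct_fcs,
                                    screen_cfg$positivity_threshold_pct)
  tab$variable <- tab$positive &
    (tab$fold >= screen_cfg$variable_fold_min |
       abs(tab$pct_plt - tab$pct_fcs) >= screen_cfg$variable_diff_pct)
  tab$enriched <- tab$variable & flag_enriched(tab$fold, p_used, screen_cfg)
  rownames(tab) <- NULL

  out <- list(markers = tab, percent_positive = pct_long,
              stain_index = si_long,
              background = if (inherits(run, "screen_run"))
                run$background else NULL,
              populations = c(ref_pop, num_pop))
  class(out) <- "screen_result"
  out
}

#' @export
print.screen_result <- function(x, ...) {
  tab <- x$markers
  cat("screen_result:", nrow(tab), "markers |",
      sum(tab$positive), "positive |",
      sum(tab$variable), "variable |",
      sum(tab$enriched), "enriched\n")
  invisible(x)
}

#' Full-precision TSV helpers
#'
#' Write a data.frame with numeric columns rendered at 17 significant
#' digits (lossless double round-trip), and read it back.
#'
#' @param df data.frame
#' @param path file path
#' @return `read_tsv_num` returns the data.frame
#' @export
write_tsv_num <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_num
#' @export
read_tsv_num <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = c("NA", "nan"))
}

.write_num_tsv <- write_tsv_num
.read_num_tsv <- read_tsv_num

#' Write the screen result tables to a directory
#'
#' Writes `markers.tsv` (classification flags, folds, p-values, stain
#' indices), `percent_positive.tsv` and `stain_index.tsv` (per marker x
#' donor x population), and `background.tsv`. All numeric columns
#' round-trip losslessly.
#'
#' @param result `screen_result`
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_num_tsv(result$markers, file.path(out_dir, "markers.tsv"))
  .write_num_tsv(result$percent_positive,
                 file.path(out_dir, "percent_positive.tsv"))
  .write_num_tsv(result$stain_index, file.path(out_dir, "stain_index.tsv"))
  if (!is.null(result$background)) {
    bg <- result$background
    bg$ratio <- rep(attr(result$background, "ratio") %||% NA_real_,
                    nrow(bg))
    .write_num_tsv(bg, file.path(out_dir, "background.tsv"))
  }
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read back a written screen result
#' @param dir directory written by [write_results()]
#' @return list of class `screen_result`
#' @export
read_results <- function(dir) {
  out <- list(
    markers = .read_num_tsv(file.path(dir, "markers.tsv")),
    percent_positive = .read_num_tsv(file.path(dir, "percent_positive.tsv")),
    stain_index = .read_num_tsv(file.path(dir, "stain_index.tsv")))
  bg_path <- file.path(dir, "background.tsv")
  if (file.exists(bg_path)) {
    bg <- .read_num_tsv(bg_path)
    ratio <- if (nrow(bg) > 0) bg$ratio[1] else NA_real_
    bg$ratio <- NULL
    attr(bg, "ratio") <- ratio
    out$background <- bg
  }
  class(out) <- "screen_result"
  out
}
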