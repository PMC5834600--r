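# Fixture builders: small layouts and simulation configs assembled in code.

tiny_layout <- function(markers = c("MK1", "MK2", "MK3", "MK4"),
                        n_iso = 2, unstained = TRUE, plate = "P1") {
  grid <- well_grid()
  iso_names <- paste0("IgG", seq_len(n_iso), "-", plate)
  rows <- list()
  idx <- 1L
  for (g in seq_len(n_iso)) {
    rows[[idx]] <- data.frame(plate = plate, well = grid[idx],
                              reagent_name = iso_names[g],
                              reagent_class = "isotype",
                              isotype_group = iso_names[g],
                              stringsAsFactors = FALSE)
    idx <- idx + 1L
  }
  if (unstained) {
    rows[[idx]] <- data.frame(plate = plate, well = grid[idx],
                              reagent_name = "unstained",
                              reagent_class = "unstained",
                              isotype_group = NA_character_,
                              stringsAsFactors = FALSE)
    idx <- idx + 1L
  }
  for (j in seq_along(markers)) {
    rows[[idx]] <- data.frame(plate = plate, well = grid[idx],
                              reagent_name = markers[j],
                              reagent_class = "marker",
                              isotype_group = iso_names[((j - 1L) %% n_iso) + 1L],
                              stringsAsFactors = FALSE)
    idx <- idx + 1L
  }
  validate_layout(do.call(rbind, rows))
}

tiny_config <- function(markers = tiny_truth(),
                        layout = tiny_layout(markers$marker),
                        events_per_well = 20000L,
                        debris_fraction = 0, doublet_fraction = 0,
                        populations = default_populations(),
                        n_donors = 1L, seed = 42L, ...) {
  plate_sim_config(layout = layout, populations = populations,
                   markers = markers, events_per_well = events_per_well,
                   debris_fraction = debris_fraction,
                   doublet_fraction = doublet_fraction,
                   n_donors = n_donors, seed = seed, ...)
}

tiny_truth <- function(markers = c("MK1", "MK2", "MK3", "MK4"),
                       f1 = c(0.6, 0.5, 0.3, 0),
                       f2 = c(0.2, 0.5, 0.3, 0),
                       donor_logit_sd = 0) {
  marker_truth(markers, f1, f2, positive_logshift = 3,
               donor_logit_sd = donor_logit_sd)
}

# gate config sized for small synthetic wells
tiny_gate_config <- function(...) {
  gate_config(min_events_per_well = 1000L, ...)
}

# first marker well of a layout
first_marker_well <- function(layout) {
  layout[layout$reagent_class == "marker", ][1, ]
}
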