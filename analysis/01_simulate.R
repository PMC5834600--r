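#!/usr/bin/env Rscript
# Step 1: define the synthetic screen and record its planted ground truth.
#
# Writes the planted marker truth and the realized donor-level positive
# fractions, the quantities every later step is judged against.

source("analysis/00_config.R")

cfg <- make_screen_config()
out <- file.path(RESULTS_DIR, "sim")
dir.create(out, showWarnings = FALSE)

write_panel_layout(cfg$layout, file.path(out, "panel_layout.tsv"))
write_tsv_num(as.data.frame(cfg$markers),
              file.path(out, "marker_truth.tsv"))
donor_fr <- draw_donor_fractions(cfg)
write_tsv_num(donor_fr, file.path(out, "donor_fractions.tsv"))

enr <- cfg$markers$marker[cfg$markers$frac_pop1 > cfg$markers$frac_pop2]
cat("screen design:", nrow(cfg$layout), "wells over",
    length(unique(cfg$layout$plate)), "plates;",
    sum(cfg$layout$reagent_class == "marker"), "markers,",
    sum(cfg$layout$reagent_class == "isotype"), "isotype controls\n")
cat("planted enriched markers (", length(enr), "): ",
    paste(enr, collapse = ", "), "\n", sep = "")
cat("donors:", cfg$n_donors, "| events/well:", cfg$events_per_well,
    "| pooling ratio:", cfg$pooling_ratio, "\n")
cat("wrote", file.path(out, c("panel_layout.tsv", "marker_truth.tsv",
                              "donor_fractions.tsv")), sep = "\n  ")
cat("\n")
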