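#!/usr/bin/env Rscript
# Step 3: marker-level statistics and the enrichment filter.
#
# Aggregates the gated well statistics across donors: percent positive,
# fold increase (floored denominator), one-way ANOVA, the 5.5% positivity
# rule and the fold >= 1.5 & p < 0.05 enrichment filter; compares the
# called enriched set against the planted one.

source("analysis/00_config.R")

gated <- file.path(RESULTS_DIR, "gated")
well_stats <- read_tsv_num(file.path(gated, "well_stats.tsv"))
marker_truth_tab <- read_tsv_num(file.path(RESULTS_DIR, "sim",
                                           "marker_truth.tsv"))

res <- screen_markers(well_stats, make_screen_stats_config(),
                      populations = c("FCS", "PLT"))
bg <- read_tsv_num(file.path(gated, "background.tsv"))
attr(bg, "ratio") <- bg$ratio[1]
res$background <- bg

out <- file.path(RESULTS_DIR, "screen")
write_results(res, out)

tab <- res$markers
cat("markers analysed:", nrow(tab), "\n")
cat("positive:", sum(tab$positive), "| variable:", sum(tab$variable),
    "| enriched:", sum(tab$enriched), "\n")
cat("enriched markers:",
    paste(sort(tab$marker[tab$enriched]), collapse = ", "), "\n")

planted_enr <- marker_truth_tab$marker[
  marker_truth_tab$frac_pop1 > marker_truth_tab$frac_pop2]
found <- tab$marker[tab$enriched]
cat("recovery vs planted truth:", sum(found %in% planted_enr), "of",
    length(planted_enr), "planted enriched recovered;",
    sum(!found %in% planted_enr), "false positives\n")
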