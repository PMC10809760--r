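#!/usr/bin/env Rscript
# Fit exponential decay to the aerobic and nitrogen guilds in the ferruginous
# zone (depth -> age via each site's sedimentation rate) and exponential
# growth to the fermenters in the 6.5-9.5 cm window; report half-lives,
# doubling times, and cross-site ranges, against the planted truth.

suppressMessages(library(hadalguilds))

coverage <- read_table("results/sim/coverage.tsv", "coverage_matrix")
meta <- read_table("results/sample_metadata_zoned.tsv", "sample_metadata")
asn <- readr::read_tsv("results/guild_assignments.tsv", show_col_types = FALSE)
truth <- readr::read_tsv("results/sim/kinetics_truth.tsv", show_col_types = FALSE)

guilds <- aggregate_groups(relative_abundance(coverage), guild_mapping(asn))

decay <- fit_guild_kinetics(guilds, meta, groups = c("aerobic", "nitrogen"),
                            direction = "decay")
growth <- fit_guild_kinetics(guilds, meta, groups = "fermenter",
                             direction = "growth")

fits <- dplyr::bind_rows(decay$fits, growth$fits)
readr::write_tsv(fits, "results/kinetic_fits.tsv")
readr::write_tsv(dplyr::bind_rows(decay$range, growth$range),
                 "results/kinetic_ranges.tsv")

for (g in c("aerobic", "nitrogen")) {
  r <- decay$range[decay$range$group == g, ]
  message(sprintf("%s half-lives range %.0f-%.0f yr across %d sites",
                  g, r$half_life_min, r$half_life_max, r$n_sites))
}
f <- growth$fits
message(sprintf("fermenter doubling times: %s yr (planted: %s yr)",
                paste(round(sort(f$half_life), 1), collapse = ", "),
                paste(round(sort(truth$doubling_time_yr), 1), collapse = ", ")))
aero <- decay$fits[decay$fits$group == "aerobic", ]
aero <- aero[order(aero$site_id), ]
err <- abs(aero$half_life - truth$half_life_yr) / truth$half_life_yr
message(sprintf("aerobic recovery error vs planted: median %.1f%%, max %.1f%%",
                100 * median(err), 100 * max(err)))
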