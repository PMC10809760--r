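#!/usr/bin/env Rscript
# Build abundance-weighted depth profiles: per-sample relative abundances,
# guild profiles (mean +/- SE across sites per horizon), CAZyme family
# abundances, and the eight secreted-CAZyme strata.

suppressMessages(library(hadalguilds))

coverage <- read_table("results/sim/coverage.tsv", "coverage_matrix")
meta <- read_table("results/sample_metadata_zoned.tsv", "sample_metadata")
caz <- read_table("results/sim/cazyme_table.tsv", "cazyme_table")
asn <- readr::read_tsv("results/guild_assignments.tsv", show_col_types = FALSE)

ra <- relative_abundance(coverage)
guilds <- aggregate_groups(ra, guild_mapping(asn))
prof <- depth_profile(guilds, meta)
readr::write_tsv(prof, "results/guild_depth_profiles.tsv")

strata <- secreted_cazyme_strata(caz, rownames(ra))
strata_ab <- aggregate_groups(ra, tibble::tibble(mag_id = strata$mag_id,
                                                 group = as.character(strata$stratum)))
readr::write_tsv(depth_profile(strata_ab, meta),
                 "results/strata_depth_profiles.tsv")
readr::write_tsv(strata, "results/cazyme_strata.tsv")

fam <- cazyme_family_abundance(ra, caz)
readr::write_tsv(tibble::as_tibble(as.data.frame(fam), rownames = "cazyme_family"),
                 "results/cazyme_family_abundance.tsv")

surface <- prof[prof$depth_top_cm == 0, ]
message("surface guild abundances (mean +/- SE across sites):")
for (i in seq_len(nrow(surface))) {
  message(sprintf("  %-12s %5.1f%% +/- %.1f%%", surface$group[i],
                  100 * surface$mean[i], 100 * surface$se[i]))
}
message(sprintf("strata populated: %s",
                paste(levels(strata$stratum)[table(strata$stratum) > 0],
                      collapse = ", ")))
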