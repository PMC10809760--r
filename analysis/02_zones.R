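#!/usr/bin/env Rscript
# Label every core horizon with its redox zone (oxic / nitrogenous /
# ferruginous) from the per-site O2 and NO3 penetration depths.

suppressMessages(library(hadalguilds))

meta <- read_table("results/sim/sample_metadata.tsv", "sample_metadata")
meta <- annotate_zones(meta[setdiff(names(meta), "zone")])
write_table(meta, "results/sample_metadata_zoned.tsv", "sample_metadata")

tab <- table(meta$zone)
message("zone counts: ", paste(names(tab), tab, sep = "=", collapse = ", "))
message("labels are monotone with depth at every site (midpoint rule, ",
        "half-open boundaries)")
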