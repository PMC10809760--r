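#!/usr/bin/env Rscript
# Statistics layer over the profiles: Bray-Curtis PCoA of MAG relative
# abundances, PERMANOVA (global + pairwise, FDR) of redox zones, Hellinger
# PCA of CAZyme family abundances, Welch's t between zone means, and Ward
# ordering of guild profiles for heatmap columns.

suppressMessages(library(hadalguilds))

seed <- 1L
coverage <- read_table("results/sim/coverage.tsv", "coverage_matrix")
meta <- read_table("results/sample_metadata_zoned.tsv", "sample_metadata")
fam <- as.matrix(tibble::column_to_rownames(
  readr::read_tsv("results/cazyme_family_abundance.tsv", show_col_types = FALSE),
  "cazyme_family"))
asn <- readr::read_tsv("results/guild_assignments.tsv", show_col_types = FALSE)

ra <- relative_abundance(coverage)
zones <- meta$zone[match(colnames(ra), meta$sample_id)]

d <- bray_curtis(t(ra))
ord <- pcoa(d)
coords <- tibble::as_tibble(as.data.frame(ord$coordinates[, 1:2]),
                            rownames = "sample_id")
coords$zone <- zones
readr::write_tsv(coords, "results/pcoa_bray_zones.tsv")
message(sprintf("Bray-Curtis PCoA: axes 1+2 explain %.0f%% of variance",
                100 * sum(ord$prop_variance[1:2])))

glob <- permanova(d, zones, n_perm = 999, seed = seed)
pw <- pairwise_permanova(d, zones, n_perm = 999, seed = seed)
readr::write_tsv(pw, "results/permanova_pairwise_zones.tsv")
message(sprintf("global PERMANOVA: pseudo-F = %.1f, p = %.3f",
                glob$pseudo_f, glob$p_value))
message(sprintf("pairwise (fdr-adjusted p): %s",
                paste(sprintf("%s~%s %.3f", pw$group_a, pw$group_b,
                              pw$p_adjusted), collapse = "; ")))

hel <- hellinger(t(fam))
hp <- pca(hel)
readr::write_tsv(tibble::as_tibble(as.data.frame(hp$coordinates[, 1:2]),
                                   rownames = "sample_id"),
                 "results/pca_hellinger_cazymes.tsv")
message(sprintf("Hellinger PCA of CAZyme abundances: PC1 %.0f%%, PC2 %.0f%%",
                100 * hp$prop_variance[1], 100 * hp$prop_variance[2]))

# Welch's t: aerobic-guild abundance, nitrogenous vs ferruginous samples
guilds <- aggregate_groups(ra, guild_mapping(asn))
aero <- guilds["aerobic", ]
wt <- welch_t(aero[zones == "nitrogenous"], aero[zones == "ferruginous"])
message(sprintf("aerobic guild, nitrogenous vs ferruginous: Welch t = %.1f, p = %.2g",
                wt$t, wt$p_value))

# Ward ordering of guild median-abundance profiles (heatmap column order)
med <- do.call(cbind, lapply(split(seq_along(zones), zones),
                             function(ix) apply(guilds[, ix, drop = FALSE], 1,
                                                median)))
wo <- ward_order(med)
message("Ward leaf order of guilds: ", paste(wo$order, collapse = " < "))
readr::write_tsv(tibble::tibble(order = seq_along(wo$order), group = wo$order),
                 "results/ward_guild_order.tsv")
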