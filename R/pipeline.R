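#' Run the full analysis pipeline on one configuration
#'
#' Orchestrates simulate/load -> zone annotation -> guild classification ->
#' abundance profiles -> kinetics -> ordination and writes every stage table
#' plus a run manifest under `outdir`. Identical `config` and seed give a
#' byte-identical bundle.
#'
#' @param config A list. Either `config$simulate = sim_config(...)` to run on
#'   a synthetic community, or `config$paths`, a named list of the seven input
#'   TSVs (`catalog`, `genes`, `metal_flags`, `cazymes`, `coverage`,
#'   `metadata`, `modules`). Optional elements: `override_families`,
#'   `boundary_buffer_cm`, `strata_scheme`, `growth_window_cm`, `n_perm`.
#' @param seed Integer seed for every stochastic stage.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, seed = 1L, outdir = "results/pipeline") {
  t0 <- Sys.time()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name) rlang::inform(paste0("[", name, "]"))

  stage("inputs")
  if (!is.null(config$simulate)) {
    sim <- simulate_community(config$simulate, seed = seed)
    catalog <- sim$catalog; gene_table <- sim$gene_table
    metal_flags <- sim$metal_flags; cazyme_table <- sim$cazyme_table
    coverage <- sim$coverage; metadata <- sim$metadata
    modules <- default_oxidase_modules()
    write_table(catalog, file.path(outdir, "mag_catalog.tsv"), "mag_catalog")
    write_table(gene_table, file.path(outdir, "gene_table.tsv"), "gene_table")
    write_table(metal_flags, file.path(outdir, "metal_flags.tsv"),
                "metal_flag_table")
    write_table(cazyme_table, file.path(outdir, "cazyme_table.tsv"),
                "cazyme_table")
    write_table(coverage, file.path(outdir, "coverage.tsv"), "coverage_matrix")
    readr::write_tsv(sim$ground_truth, file.path(outdir, "ground_truth.tsv"))
    readr::write_tsv(sim$kinetics_truth,
                     file.path(outdir, "kinetics_truth.tsv"))
  } else if (!is.null(config$paths)) {
    p <- config$paths
    need <- c("catalog", "genes", "metal_flags", "cazymes", "coverage",
              "metadata")
    miss <- setdiff(need, names(p))
    if (length(miss)) {
      rlang::abort(paste0("run_pipeline: config$paths is missing: ",
                          paste(miss, collapse = ", ")),
                   class = "hadalguilds_config_error")
    }
    catalog <- read_table(p$catalog, "mag_catalog")
    gene_table <- read_table(p$genes, "gene_table")
    metal_flags <- read_table(p$metal_flags, "metal_flag_table")
    cazyme_table <- read_table(p$cazymes, "cazyme_table")
    coverage <- read_table(p$coverage, "coverage_matrix")
    metadata <- read_table(p$metadata, "sample_metadata")
    modules <- if (!is.null(p$modules)) {
      module_list(read_table(p$modules, "module_definitions"))
    } else {
      default_oxidase_modules()
    }
    sim <- NULL
  } else {
    rlang::abort("run_pipeline: config needs either $simulate or $paths",
                 class = "hadalguilds_config_error")
  }

  stage("zones")
  metadata <- annotate_zones(metadata,
                             boundary_buffer_cm = config$boundary_buffer_cm %||% 0)
  write_table(metadata, file.path(outdir, "sample_metadata.tsv"),
              "sample_metadata")

  stage("classify")
  assignments <- classify_guilds(
    catalog, gene_table, metal_flags, modules,
    override_families = config$override_families %||% "Nitrosopumilaceae")
  overlap <- guild_overlap(assignments)
  readr::write_tsv(assignments, file.path(outdir, "guild_assignments.tsv"))
  readr::write_tsv(overlap, file.path(outdir, "guild_overlap.tsv"))

  stage("profiles")
  relabund <- relative_abundance(coverage)
  guild_abund <- aggregate_groups(relabund, guild_mapping(assignments))
  profiles <- depth_profile(guild_abund, metadata)
  strata <- secreted_cazyme_strata(cazyme_table, catalog$mag_id,
                                   scheme = config$strata_scheme %||%
                                     default_strata_scheme())
  strata_abund <- aggregate_groups(
    relabund, tibble::tibble(mag_id = strata$mag_id,
                             group = as.character(strata$stratum)))
  fam_abund <- cazyme_family_abundance(relabund, cazyme_table)
  readr::write_tsv(profiles, file.path(outdir, "guild_depth_profiles.tsv"))
  readr::write_tsv(strata, file.path(outdir, "cazyme_strata.tsv"))
  readr::write_tsv(tibble::as_tibble(as.data.frame(fam_abund),
                                     rownames = "cazyme_family"),
                   file.path(outdir, "cazyme_family_abundance.tsv"))

  stage("kinetics")
  decay <- fit_guild_kinetics(guild_abund, metadata,
                              groups = c("aerobic", "nitrogen"),
                              direction = "decay")
  growth <- fit_guild_kinetics(guild_abund, metadata, groups = "fermenter",
                               direction = "growth",
                               window = config$growth_window_cm %||% c(6.5, 9.5))
  kin <- dplyr::bind_rows(decay$fits, growth$fits)
  readr::write_tsv(kin, file.path(outdir, "kinetic_fits.tsv"))
  readr::write_tsv(dplyr::bind_rows(decay$range, growth$range),
                   file.path(outdir, "kinetic_ranges.tsv"))

  stage("ordination")
  n_perm <- config$n_perm %||% 999
  bc <- bray_curtis(t(relabund))
  ord_bc <- pcoa(bc)
  perm <- permanova(bc, metadata$zone[match(colnames(relabund),
                                            metadata$sample_id)],
                    n_perm = n_perm, seed = seed)
  hel <- hellinger(t(fam_abund))
  ord_pca <- pca(hel)
  coords <- tibble::as_tibble(as.data.frame(ord_bc$coordinates[, 1:2]),
                              rownames = "sample_id")
  readr::write_tsv(coords, file.path(outdir, "pcoa_coordinates.tsv"))
  readr::write_tsv(perm, file.path(outdir, "permanova_zone.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("hadalguilds")),
    seed = seed,
    config_hash = rlang::hash(config),
    created = format(t0, "%Y-%m-%dT%H:%M:%S"),
    rows = list(catalog = nrow(catalog), gene_table = nrow(gene_table),
                cazyme_table = nrow(cazyme_table),
                samples = nrow(metadata),
                assignments = nrow(assignments),
                kinetic_fits = nrow(kin))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(metadata = metadata, assignments = assignments,
                 overlap = overlap, relabund = relabund,
                 guild_abund = guild_abund, profiles = profiles,
                 strata = strata, kinetics = kin,
                 ranges = dplyr::bind_rows(decay$range, growth$range),
                 pcoa = ord_bc, pca = ord_pca, permanova = perm,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
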