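#' Configuration of the synthetic hadal-core community simulator
#'
#' Encodes the study conditions the simulator emulates: six hadal sites cored
#' at 1-cm resolution to 10 cm and 2.5-cm resolution below, O2 penetration
#' depths spanning 2.6-4.1 cm, NO3 penetration around 8 cm, sedimentation
#' rates spanning 0.29-0.76 mm/yr, respirer decay half-lives spanning 135-419
#' years in the ferruginous zone, and putative fermenters doubling every
#' 1.4 cm inside a 6.5-9.5 cm growth window.
#'
#' Surface relative-abundance levels and the within-zone shape factors of the
#' non-focal guilds are free parameters of the simulator (no realism claim is
#' attached to them); a `filler` archetype (a dsrAB carrier, so it lands in
#' the sulfur guild and is never kinetically fitted) absorbs the complement so
#' that total expected coverage is exactly constant over depth — the
#' constant-total-community assumption under which relative abundance is read
#' as proportional to cell density.
#'
#' @param n_mags Named integer vector of MAGs per archetype (names:
#'   strict_aerobe, aerobe_nitrogen, nitrifier, anammox, sulfur, metal,
#'   fermenter, filler); every archetype needs >= 1.
#' @param n_sites Number of hadal sites.
#' @param max_depth_cm Core bottom, cm.
#' @param o2_penetration_cm,no3_penetration_cm,sedimentation_rate_mm_yr
#'   Per-site vectors (recycled from the defaults' bands if scalar).
#' @param half_life_yr Per-site planted respirer half-life in the ferruginous
#'   zone, years.
#' @param doubling_distance_cm Planted fermenter doubling distance, cm.
#' @param growth_window_cm Fermenter exponential-growth depth window, cm.
#' @param surface_levels Named vector of surface relative abundances per
#'   archetype (filler absorbs the remainder).
#' @param total_coverage Expected summed coverage per sample (arbitrary
#'   units).
#' @param sigma Lognormal noise sd on coverages (0 = noise-free).
#' @param water_depth_m Per-site water depths, m.
#' @return List of class `"hg_sim_config"`.
#' @export
sim_config <- function(n_mags = c(strict_aerobe = 30L, aerobe_nitrogen = 50L,
                                  nitrifier = 10L, anammox = 8L, sulfur = 10L,
                                  metal = 10L, fermenter = 40L, filler = 10L),
                       n_sites = 6L,
                       max_depth_cm = 30,
                       o2_penetration_cm = seq(2.6, 4.1, length.out = n_sites),
                       no3_penetration_cm = seq(7.6, 8.4, length.out = n_sites),
                       sedimentation_rate_mm_yr = seq(0.29, 0.76,
                                                      length.out = n_sites),
                       half_life_yr = seq(135, 419, length.out = n_sites),
                       doubling_distance_cm = 1.4,
                       growth_window_cm = c(6.5, 9.5),
                       surface_levels = c(strict_aerobe = 0.18,
                                          aerobe_nitrogen = 0.30,
                                          nitrifier = 0.15, anammox = 0.02,
                                          sulfur = 0.03, metal = 0.02,
                                          fermenter = 0.03),
                       total_coverage = 100,
                       sigma = 0.3,
                       water_depth_m = seq(7720, 8085, length.out = n_sites)) {
  archetypes <- c("strict_aerobe", "aerobe_nitrogen", "nitrifier", "anammox",
                  "sulfur", "metal", "fermenter", "filler")
  if (!all(archetypes %in% names(n_mags)) || any(n_mags[archetypes] < 1L)) {
    rlang::abort("sim_config: every archetype needs n_mags >= 1",
                 class = "hadalguilds_config_error")
  }
  rec <- function(v) rep_len(v, n_sites)
  cfg <- list(
    n_mags = as.integer(n_mags[archetypes]),
    archetypes = archetypes,
    n_sites = as.integer(n_sites),
    max_depth_cm = max_depth_cm,
    o2_penetration_cm = rec(o2_penetration_cm),
    no3_penetration_cm = rec(no3_penetration_cm),
    sedimentation_rate_mm_yr = rec(sedimentation_rate_mm_yr),
    half_life_yr = rec(half_life_yr),
    doubling_distance_cm = doubling_distance_cm,
    growth_window_cm = growth_window_cm,
    surface_levels = surface_levels,
    total_coverage = total_coverage,
    sigma = sigma,
    water_depth_m = rec(water_depth_m)
  )
  names(cfg$n_mags) <- archetypes
  if (any(cfg$sedimentation_rate_mm_yr <= 0) || any(cfg$half_life_yr <= 0) ||
      cfg$doubling_distance_cm <= 0 || cfg$sigma < 0) {
    rlang::abort("sim_config: rates, half-lives and sigma must be positive",
                 class = "hadalguilds_config_error")
  }
  if (any(cfg$no3_penetration_cm <= cfg$o2_penetration_cm)) {
    rlang::abort("sim_config: no3 penetration must exceed o2 penetration",
                 class = "hadalguilds_config_error")
  }
  structure(cfg, class = "hg_sim_config")
}

# depth grid mirroring the coring protocol: 1-cm slices to 10 cm, 2.5-cm after
sim_horizons <- function(max_depth_cm) {
  tops <- c(seq(0, 9), seq(10, max_depth_cm - 2.5, by = 2.5))
  bottoms <- c(seq(1, 10), seq(12.5, max_depth_cm, by = 2.5))
  list(top = tops, bottom = bottoms)
}

.archetype_taxonomy <- c(
  strict_aerobe  = "d__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Woeseiales;f__Woeseiaceae;g__;s__",
  aerobe_nitrogen = "d__Bacteria;p__Proteobacteria;c__Alphaproteobacteria;o__Rhodobacterales;f__Rhodobacteraceae;g__;s__",
  nitrifier      = "d__Archaea;p__Thermoproteota;c__Nitrososphaeria;o__Nitrosopumilales;f__Nitrosopumilaceae;g__;s__",
  anammox        = "d__Bacteria;p__Planctomycetota;c__Brocadiae;o__Brocadiales;f__Brocadiaceae;g__;s__",
  sulfur         = "d__Bacteria;p__Desulfobacterota;c__Desulfobacteria;o__Desulfobacterales;f__;g__;s__",
  metal          = "d__Bacteria;p__Zixibacteria;c__MSB-5A5;o__;f__;g__;s__",
  fermenter      = "d__Bacteria;p__Chloroflexota;c__Anaerolineae;o__Anaerolineales;f__Anaerolineaceae;g__;s__",
  filler         = "d__Bacteria;p__Atribacterota;c__JS1;o__;f__;g__;s__"
)

# genes planted per archetype: sufficient and necessary to trigger exactly the
# intended classifier flags (variant genes rotate deterministically by index)
.archetype_genes <- function(arch, idx) {
  switch(arch,
    strict_aerobe = c("coxA", "coxB", "coxC"),
    aerobe_nitrogen = {
      base <- c("coxA", "coxB", "coxC", "narG", "narH")
      if (idx %% 2L == 0L) c(base, "nirK", "norB", "nosZ") else base
    },
    nitrifier = c("amoA", "amoB"),
    anammox = c("ccoN", "ccoO", "ccoP", "nirS", "hzsA"),
    sulfur = c("dsrA", "dsrB"),
    metal = "omcB",
    fermenter = character(0),
    filler = c("dsrA", "dsrB")
  )
}

.cazyme_pool <- c("GH23", "GH103", "GH102", "GH5", "GH6", "GH9", "GH13",
                  "GH15", "GH16", "GH29", "GH109", "GH2", "GH3", "GH10",
                  "PL6", "PL7", "PL1", "CE1", "CBM44", "GH57")

#' Simulate the MAG catalog, annotations and ground-truth guilds
#'
#' Draws `sum(n_mags)` MAGs from the configured archetypes and emits the four
#' annotation tables plus the planted truth. Gene content per archetype is
#' exactly what its guild flags require: e.g. strict aerobes carry a complete
#' cytochrome c oxidase module and nothing else respiratory; fermenters carry
#' no respiratory markers at all but receive secreted CAZyme repertoires
#' (distinct-family counts zero-inflated geometric, so all eight secretion
#' strata are populated).
#'
#' @param config From [sim_config()].
#' @param seed Integer; fixes the output exactly.
#' @return List: `catalog`, `gene_table`, `metal_flags`, `cazyme_table`,
#'   `ground_truth` (tibble of per-MAG archetype and true guild flags).
#' @export
simulate_catalog <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "hg_sim_config"))
  withr::with_seed(seed, {
    arch <- rep(config$archetypes, config$n_mags)
    n <- length(arch)
    mag_id <- sprintf("MAG%04d", seq_len(n))
    catalog <- tibble::tibble(
      mag_id = mag_id,
      taxonomy = unname(.archetype_taxonomy[arch]),
      completeness = round(stats::runif(n, 75, 100), 1),
      redundancy = round(stats::runif(n, 0, 9.9), 1),
      genome_size = round(stats::runif(n, 1.5e6, 6e6))
    )

    gene_rows <- lapply(seq_len(n), function(i) {
      g <- .archetype_genes(arch[i], i)
      if (length(g) == 0L) return(NULL)
      tibble::tibble(mag_id = mag_id[i], feature_id = g,
                     copies = 1L + stats::rpois(length(g), 0.2))
    })
    gene_table <- dplyr::bind_rows(gene_rows)

    metal_flags <- tibble::tibble(mag_id = mag_id,
                                  porin_cytochrome_homolog = arch == "metal")

    caz_rows <- lapply(seq_len(n), function(i) {
      if (arch[i] == "fermenter") {
        # zero-inflated geometric on the number of distinct secreted families
        k <- if (stats::runif(1) < 0.15) 0L else 1L + stats::rgeom(1, 0.22)
        k <- min(k, length(.cazyme_pool))
        n_extra <- stats::rpois(1, 1)   # non-secreted families on top
      } else {
        k <- stats::rbinom(1, 2, 0.4)   # housekeeping-ish secreted lyases
        n_extra <- stats::rbinom(1, 1, 0.3)
      }
      fams <- sample(.cazyme_pool, min(k + n_extra, length(.cazyme_pool)))
      if (length(fams) == 0L) return(NULL)
      secreted <- c(rep(1L, min(k, length(fams))),
                    rep(0L, max(0L, length(fams) - k)))
      sec_copies <- ifelse(secreted == 1L, 1L + stats::rpois(length(fams), 0.5), 0L)
      tibble::tibble(mag_id = mag_id[i], cazyme_family = fams,
                     copies = sec_copies + 1L + stats::rpois(length(fams), 0.3),
                     secreted_copies = sec_copies)
    })
    cazyme_table <- dplyr::bind_rows(caz_rows)

    ground_truth <- tibble::tibble(
      mag_id = mag_id,
      archetype = arch,
      aerobic = arch %in% c("strict_aerobe", "aerobe_nitrogen", "nitrifier",
                            "anammox"),
      nitrogen = arch %in% c("aerobe_nitrogen", "anammox"),
      sulfur_resp = arch %in% c("sulfur", "filler"),
      metal_resp = arch == "metal",
      fermenter = arch == "fermenter"
    )

    list(catalog = validate_table(catalog, "mag_catalog"),
         gene_table = validate_table(gene_table, "gene_table"),
         metal_flags = validate_table(metal_flags, "metal_flag_table"),
         cazyme_table = validate_table(cazyme_table, "cazyme_table"),
         ground_truth = ground_truth)
  })
}

# expected relative abundance of one archetype at depth z (cm) for one site.
# Piecewise log-linear in age with C0 continuity; above the ferruginous top
# the shapes are free simulator parameters, below it every respirer archetype
# decays with the site's planted rate so guild sums stay exactly exponential.
.archetype_shape <- function(arch, z, site, cfg) {
  s0 <- cfg$surface_levels
  no3 <- cfg$no3_penetration_cm[site]
  omega <- cfg$sedimentation_rate_mm_yr[site]
  lambda <- log(2) / cfg$half_life_yr[site]        # 1/yr
  age <- function(zz) 10 * zz / omega
  # the pre-ferruginous shapes below are all capped at z = no3 (pmin), so for
  # z >= no3 `base` holds the ferruginous-top level and the decay factor
  # multiplies in C0-continuously
  base <- switch(arch,
    strict_aerobe = rep(s0[["strict_aerobe"]], length(z)),
    aerobe_nitrogen = s0[["aerobe_nitrogen"]] *
      exp(log(1.2) * pmin(z, no3) / no3),          # rises to a mid-core peak
    nitrifier = s0[["nitrifier"]] * 2^(-pmin(z, no3) / 10),  # surface peak
    anammox = s0[["anammox"]] * exp(log(2.5) * pmin(z, no3) / no3),
    sulfur = s0[["sulfur"]] * exp(log(2) * pmin(z, no3) / no3),
    metal = s0[["metal"]] * exp(log(2) * pmin(z, no3) / no3),
    fermenter = {
      gw <- cfg$growth_window_cm
      zeff <- pmin(pmax(z, gw[1]), gw[2])
      s0[["fermenter"]] * 2^((zeff - gw[1]) / cfg$doubling_distance_cm)
    },
    rlang::abort(paste0("unknown archetype ", arch))
  )
  if (arch %in% c("strict_aerobe", "aerobe_nitrogen", "nitrifier", "anammox")) {
    fe <- z >= no3
    decay <- ifelse(fe, exp(-lambda * (age(z) - age(no3))), 1)
    base * decay
  } else {
    base
  }
}

#' Expected relative-abundance trajectories (noise-free truth)
#'
#' @param config From [sim_config()].
#' @param depth_mid_cm Horizon midpoints, cm.
#' @param site Site index.
#' @return Matrix, archetypes x depths, columns summing to 1 (the `filler`
#'   archetype absorbs the complement).
#' @export
archetype_trajectories <- function(config, depth_mid_cm, site) {
  named <- setdiff(config$archetypes, "filler")
  m <- do.call(rbind, lapply(named, function(a) {
    .archetype_shape(a, depth_mid_cm, site, config)
  }))
  rownames(m) <- named
  filler <- 1 - colSums(m)
  if (any(filler <= 0)) {
    rlang::abort(paste0("simulate_core: archetype shapes exceed the total at ",
                        "depth ", depth_mid_cm[which(filler <= 0)[1]],
                        " cm; lower surface_levels"),
                 class = "hadalguilds_config_error")
  }
  rbind(m, filler = filler)
}

#' Simulate coverage matrix and sample metadata for the planted community
#'
#' Expected coverage of MAG i in a sample is its archetype's trajectory at the
#' horizon midpoint times a fixed per-MAG weight (weights sum to 1 within the
#' archetype), scaled to a constant total coverage; observed coverage
#' multiplies in lognormal(0, sigma) noise. Ages are implied by depth and the
#' site's sedimentation rate; zone labels derive from the penetration depths.
#'
#' @param catalog,ground_truth From [simulate_catalog()].
#' @param config From [sim_config()].
#' @param seed Integer seed.
#' @return List: `coverage` (matrix), `metadata` (`sample_metadata` with
#'   zones), `expected_relabund` (noise-free MAG x sample truth),
#'   `kinetics_truth` (tibble: site_id, planted half_life_yr /
#'   doubling_time_yr and windows).
#' @export
simulate_core <- function(catalog, ground_truth, config = sim_config(),
                          seed = 1L) {
  stopifnot(inherits(config, "hg_sim_config"))
  hz <- sim_horizons(config$max_depth_cm)
  if (any(hz$top < 0) || any(diff(hz$top) <= 0)) {
    rlang::abort("simulate_core: horizon grid must start at 0 and be monotone",
                 class = "hadalguilds_config_error")
  }
  mid <- (hz$top + hz$bottom) / 2
  sites <- sprintf("H%d", seq_len(config$n_sites))

  withr::with_seed(seed, {
    # fixed per-MAG weights within each archetype (lognormal, normalized)
    w <- stats::setNames(numeric(nrow(ground_truth)), ground_truth$mag_id)
    for (a in config$archetypes) {
      idx <- ground_truth$archetype == a
      wi <- stats::rlnorm(sum(idx), 0, 0.5)
      w[idx] <- wi / sum(wi)
    }

    meta_rows <- list()
    cov_cols <- list()
    exp_cols <- list()
    for (s in seq_along(sites)) {
      traj <- archetype_trajectories(config, mid, s)
      sample_ids <- sprintf("%s_%03.0f", sites[s], hz$top * 10)
      meta_rows[[s]] <- tibble::tibble(
        sample_id = sample_ids,
        site_id = sites[s],
        depth_top_cm = hz$top,
        depth_bottom_cm = hz$bottom,
        water_depth_m = config$water_depth_m[s],
        o2_penetration_cm = config$o2_penetration_cm[s],
        no3_penetration_cm = config$no3_penetration_cm[s],
        sedimentation_rate_mm_yr = config$sedimentation_rate_mm_yr[s]
      )
      p_exp <- traj[ground_truth$archetype, , drop = FALSE] * w
      dimnames(p_exp) <- list(ground_truth$mag_id, sample_ids)
      noise <- matrix(stats::rlnorm(length(p_exp), 0, config$sigma),
                      nrow = nrow(p_exp))
      cov_cols[[s]] <- p_exp * config$total_coverage * noise
      exp_cols[[s]] <- p_exp
    }
    coverage <- do.call(cbind, cov_cols)
    expected <- do.call(cbind, exp_cols)
    metadata <- dplyr::bind_rows(meta_rows)
    metadata$zone <- assign_zone(metadata$depth_top_cm, metadata$depth_bottom_cm,
                                 metadata$o2_penetration_cm,
                                 metadata$no3_penetration_cm)
    kinetics_truth <- tibble::tibble(
      site_id = sites,
      half_life_yr = config$half_life_yr,
      decay_window_top_cm = config$no3_penetration_cm,
      decay_window_bottom_cm = config$max_depth_cm,
      doubling_distance_cm = config$doubling_distance_cm,
      doubling_time_yr = 10 * config$doubling_distance_cm /
        config$sedimentation_rate_mm_yr,
      growth_window_top_cm = config$growth_window_cm[1],
      growth_window_bottom_cm = config$growth_window_cm[2]
    )
    list(coverage = validate_table(coverage, "coverage_matrix"),
         metadata = validate_table(metadata, "sample_metadata"),
         expected_relabund = expected,
         kinetics_truth = kinetics_truth)
  })
}

#' One-call synthetic community: catalog + core
#'
#' @param config From [sim_config()].
#' @param seed Integer seed (catalog and core derive sub-seeds from it).
#' @return List merging [simulate_catalog()] and [simulate_core()] outputs.
#' @export
simulate_community <- function(config = sim_config(), seed = 1L) {
  cat_part <- simulate_catalog(config, seed = seed)
  core_part <- simulate_core(cat_part$catalog, cat_part$ground_truth, config,
                             seed = seed + 1L)
  c(cat_part, core_part)
}
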