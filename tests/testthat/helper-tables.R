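# Random valid tables for round-trip / invariant property tests.

rand_mag_catalog <- function(n = 5) {
  tibble::tibble(
    mag_id = sprintf("MAG%04d", sample.int(9999, n)),
    taxonomy = replicate(n, paste0(
      "d__Bacteria;p__P", sample(9, 1), ";c__;o__;f__F", sample(9, 1),
      ";g__;s__")),
    completeness = round(runif(n, 75, 100), 2),
    redundancy = round(runif(n, 0, 9.9), 2),
    genome_size = round(runif(n, 1e6, 8e6))
  )
}

rand_gene_table <- function(catalog, n = 12) {
  feats <- c("coxA", "narG", "narH", "nosZ", "dsrA", "dsrB", "nirK", "amoA")
  g <- expand.grid(mag_id = catalog$mag_id, feature_id = feats,
                   stringsAsFactors = FALSE)
  g <- g[sample.int(nrow(g), min(n, nrow(g))), ]
  tibble::tibble(mag_id = g$mag_id, feature_id = g$feature_id,
                 copies = sample(1:4, nrow(g), replace = TRUE))
}

rand_cazyme_table <- function(catalog, n = 10) {
  fams <- c("GH23", "GH5", "PL7", "CBM44", "CE1", "AA3", "GT2")
  g <- expand.grid(mag_id = catalog$mag_id, cazyme_family = fams,
                   stringsAsFactors = FALSE)
  g <- g[sample.int(nrow(g), min(n, nrow(g))), ]
  copies <- sample(1:5, nrow(g), replace = TRUE)
  tibble::tibble(mag_id = g$mag_id, cazyme_family = g$cazyme_family,
                 copies = copies,
                 secreted_copies = vapply(copies, function(k) sample(0:k, 1),
                                          integer(1)))
}

rand_coverage <- function(n_mags = 6, n_samples = 4) {
  m <- matrix(round(rlnorm(n_mags * n_samples, 2, 1), 6),
              nrow = n_mags,
              dimnames = list(sprintf("MAG%04d", seq_len(n_mags)),
                              sprintf("S%02d", seq_len(n_samples))))
  m
}

rand_metadata <- function(n_sites = 2, n_horizons = 5) {
  rows <- lapply(seq_len(n_sites), function(s) {
    top <- seq(0, n_horizons - 1)
    tibble::tibble(
      sample_id = sprintf("T%d_%02d", s, top),
      site_id = paste0("T", s),
      depth_top_cm = top,
      depth_bottom_cm = top + 1,
      water_depth_m = 8000 + s,
      o2_penetration_cm = runif(1, 2.6, 4.1),
      no3_penetration_cm = runif(1, 7.6, 8.4),
      sedimentation_rate_mm_yr = runif(1, 0.29, 0.76)
    )
  })
  dplyr::bind_rows(rows)
}

rand_metal_flags <- function(catalog) {
  tibble::tibble(mag_id = catalog$mag_id,
                 porin_cytochrome_homolog = runif(nrow(catalog)) < 0.3)
}

tiny_sim_config <- function(...) {
  sim_config(n_mags = c(strict_aerobe = 6L, aerobe_nitrogen = 8L,
                        nitrifier = 3L, anammox = 2L, sulfur = 3L,
                        metal = 3L, fermenter = 8L, filler = 3L), ...)
}
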