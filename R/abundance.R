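#' Relative abundance of MAGs from mean coverages
#'
#' Each MAG's relative abundance in a sample is its mean coverage divided by
#' the summed mean coverage of all MAGs in that sample. Samples with zero
#' total coverage are left all-zero (with a warning) rather than becoming NaN.
#'
#' @param coverage Numeric matrix, MAGs x samples (see [read_table()]).
#' @return Matrix of the same shape; columns with nonzero total sum to 1.
#' @export
relative_abundance <- function(coverage) {
  coverage <- validate_table(coverage, "coverage_matrix")
  tot <- colSums(coverage)
  zero <- tot == 0
  if (any(zero)) {
    rlang::warn(paste0("relative_abundance: all-zero coverage in sample(s) ",
                       paste(colnames(coverage)[zero], collapse = ", "),
                       "; left as zeros"))
    tot[zero] <- 1
  }
  sweep(coverage, 2, tot, "/")
}

#' Aggregate MAG relative abundances into groups
#'
#' Sums member abundances per group and sample. The mapping may assign a MAG
#' to several groups (e.g. a MAG capable of both aerobic and nitrogen
#' respiration contributes its full abundance to both guilds); when the
#' mapping is a partition, group columns sum to the per-sample totals.
#' Catalog MAGs missing from the mapping go to group `"unassigned"`.
#'
#' @param relabund Matrix from [relative_abundance()] (MAGs x samples).
#' @param mapping Tibble with columns `mag_id`, `group` (one row per
#'   membership).
#' @return Matrix, groups x samples.
#' @export
aggregate_groups <- function(relabund, mapping) {
  if (!all(c("mag_id", "group") %in% names(mapping))) {
    rlang::abort("aggregate_groups: mapping needs columns mag_id, group")
  }
  mapping <- mapping[c("mag_id", "group")]
  unmapped <- setdiff(rownames(relabund), mapping$mag_id)
  if (length(unmapped)) {
    mapping <- dplyr::bind_rows(mapping,
                                tibble::tibble(mag_id = unmapped,
                                               group = "unassigned"))
  }
  mapping <- mapping[mapping$mag_id %in% rownames(relabund), ]
  groups <- unique(mapping$group)
  out <- matrix(0, nrow = length(groups), ncol = ncol(relabund),
                dimnames = list(groups, colnames(relabund)))
  for (g in groups) {
    ids <- mapping$mag_id[mapping$group == g]
    out[g, ] <- colSums(relabund[ids, , drop = FALSE])
  }
  out
}

#' Guild membership as a long mapping for [aggregate_groups()]
#'
#' @param assignments `guild_assignment` tibble.
#' @param capabilities Which capability columns to expand; default the five
#'   derived guilds.
#' @return Tibble `mag_id`, `group`; a MAG appears once per capability it has.
#' @export
guild_mapping <- function(assignments,
                          capabilities = c("aerobic", "nitrogen", "sulfur_resp",
                                           "metal_resp", "fermenter")) {
  assignments <- validate_table(assignments, "guild_assignment")
  dplyr::bind_rows(lapply(capabilities, function(cp) {
    tibble::tibble(mag_id = assignments$mag_id[assignments[[cp]]], group = cp)
  }))
}

#' Mean/SE depth profile of group abundances across sites
#'
#' Horizons are aligned across sites by their (top, bottom) interval; for each
#' group and horizon the mean and standard error (sd/sqrt(n)) are taken over
#' the sites possessing that horizon. Horizons present at fewer than 2 sites
#' are kept but flagged (`se` is NA).
#'
#' @param group_abund Matrix, groups x samples (from [aggregate_groups()]).
#' @param metadata `sample_metadata` tibble covering the samples.
#' @param sites Optional subset of site ids.
#' @return Tibble: group, depth_top_cm, depth_bottom_cm, depth_mid_cm, mean,
#'   se, n_sites.
#' @export
depth_profile <- function(group_abund, metadata, sites = NULL) {
  metadata <- validate_table(metadata, "sample_metadata")
  if (!is.null(sites)) metadata <- metadata[metadata$site_id %in% sites, ]
  metadata <- metadata[metadata$sample_id %in% colnames(group_abund), ]
  if (nrow(metadata) == 0L) {
    rlang::abort("depth_profile: no samples shared between abundances and metadata")
  }
  horizon <- paste(metadata$depth_top_cm, metadata$depth_bottom_cm, sep = "-")
  if (max(table(horizon)) < 2 && length(unique(metadata$site_id)) > 1) {
    rlang::abort("depth_profile: no horizon overlaps across sites")
  }
  out <- lapply(rownames(group_abund), function(g) {
    v <- group_abund[g, metadata$sample_id]
    agg <- tapply(seq_along(v), horizon, function(idx) {
      n <- length(idx)
      c(top = metadata$depth_top_cm[idx[1]],
        bottom = metadata$depth_bottom_cm[idx[1]],
        mean = mean(v[idx]),
        se = if (n >= 2) stats::sd(v[idx]) / sqrt(n) else NA_real_,
        n = n)
    })
    m <- do.call(rbind, agg)
    tibble::tibble(group = g,
                   depth_top_cm = unname(m[, "top"]),
                   depth_bottom_cm = unname(m[, "bottom"]),
                   depth_mid_cm = unname((m[, "top"] + m[, "bottom"]) / 2),
                   mean = unname(m[, "mean"]), se = unname(m[, "se"]),
                   n_sites = as.integer(m[, "n"]))
  })
  out <- dplyr::bind_rows(out)
  dplyr::arrange(out, .data$group, .data$depth_mid_cm)
}

#' Per-sample abundance of MAGs carrying each CAZyme family
#'
#' The abundance of a CAZyme family in a sample is the summed relative
#' abundance of the MAGs that contain the family at all (presence-weighted:
#' five copies contribute the same as one).
#'
#' @param relabund Matrix from [relative_abundance()].
#' @param cazyme_table `cazyme_table` tibble.
#' @return Matrix, families x samples, values in `[0, 1]`.
#' @export
cazyme_family_abundance <- function(relabund, cazyme_table) {
  cazyme_table <- validate_table(cazyme_table, "cazyme_table")
  cazyme_table <- cazyme_table[cazyme_table$mag_id %in% rownames(relabund) &
                               cazyme_table$copies >= 1L, ]
  fams <- sort(unique(cazyme_table$cazyme_family))
  out <- matrix(0, nrow = length(fams), ncol = ncol(relabund),
                dimnames = list(fams, colnames(relabund)))
  for (f in fams) {
    ids <- unique(cazyme_table$mag_id[cazyme_table$cazyme_family == f])
    out[f, ] <- colSums(relabund[ids, , drop = FALSE])
  }
  out
}

#' Default secreted-CAZyme strata scheme
#'
#' Eight bins over the count of distinct CAZyme families with a secretion
#' signal: 0, 1, 2, 3, 4, 5, 6-8, >8.
#'
#' @return Tibble with columns `label`, `lo`, `hi` (inclusive; `hi = Inf` for
#'   the open top bin).
#' @export
default_strata_scheme <- function() {
  tibble::tibble(
    label = c("0", "1", "2", "3", "4", "5", "6-8", ">8"),
    lo = c(0, 1, 2, 3, 4, 5, 6, 9),
    hi = c(0, 1, 2, 3, 4, 5, 8, Inf)
  )
}

#' Stratify MAGs by their number of secreted CAZymes
#'
#' Counts, per MAG, the distinct CAZyme families with at least one secreted
#' copy (signal-peptide positive) and bins the count with `scheme`. Counting
#' total secreted gene copies instead of distinct families is available via
#' `count_basis = "copies"`.
#'
#' @param cazyme_table `cazyme_table` tibble.
#' @param mag_ids All MAG ids to stratify; MAGs without any CAZyme rows get
#'   count 0.
#' @param scheme Bin table as in [default_strata_scheme()]; bins must tile
#'   0..Inf without gaps or overlap.
#' @param count_basis `"families"` (default) or `"copies"`.
#' @return Tibble: mag_id, secreted_count, stratum (factor ordered by bin).
#' @export
secreted_cazyme_strata <- function(cazyme_table, mag_ids,
                                   scheme = default_strata_scheme(),
                                   count_basis = c("families", "copies")) {
  count_basis <- match.arg(count_basis)
  cazyme_table <- validate_table(cazyme_table, "cazyme_table")
  scheme <- scheme[order(scheme$lo), ]
  if (scheme$lo[1] != 0 || !is.infinite(scheme$hi[nrow(scheme)]) ||
      any(scheme$lo[-1] != utils::head(scheme$hi, -1) + 1)) {
    rlang::abort("secreted_cazyme_strata: bins must tile 0..Inf without gaps/overlap",
                 class = "hadalguilds_config_error")
  }
  sec <- cazyme_table[cazyme_table$secreted_copies >= 1L, ]
  counts <- if (count_basis == "families") {
    tapply(sec$cazyme_family, sec$mag_id, function(x) length(unique(x)))
  } else {
    tapply(sec$secreted_copies, sec$mag_id, sum)
  }
  n <- stats::setNames(rep(0L, length(mag_ids)), mag_ids)
  common <- intersect(names(counts), mag_ids)
  n[common] <- as.integer(counts[common])
  idx <- vapply(n, function(k) which(k >= scheme$lo & k <= scheme$hi)[1], integer(1))
  tibble::tibble(mag_id = mag_ids,
                 secreted_count = as.integer(n),
                 stratum = factor(scheme$label[idx], levels = scheme$label))
}
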