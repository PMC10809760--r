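#' Completeness of a KEGG-style module in a gene set
#'
#' A module is an ordered list of reaction steps, each step a set of
#' alternative orthologs. Completeness is the fraction of steps for which at
#' least one alternative is present. The comparison against the 50% cutoff in
#' [classify_aerobic()] is done on step counts (`2 * hits >= n_steps`), so a
#' genome covering exactly half the steps passes.
#'
#' @param features Character vector of feature ids present in the genome.
#' @param module List of character vectors, one per step (see [module_list()]).
#' @return Fraction in `[0, 1]`; an empty feature set gives 0.
#' @export
module_completeness <- function(features, module) {
  if (length(module) == 0L) rlang::abort("module_completeness: module has no steps")
  hits <- vapply(module, function(step) any(step %in% features), logical(1))
  sum(hits) / length(hits)
}

module_passes <- function(features, module, threshold_num = 1L, threshold_den = 2L) {
  hits <- sum(vapply(module, function(step) any(step %in% features), logical(1)))
  # exact rational comparison: hits / n >= num / den
  hits * threshold_den >= length(module) * threshold_num
}

#' Built-in example terminal-oxidase module definitions
#'
#' Three-step stand-ins for the cytochrome c oxidase, cbb3-type cytochrome c
#' oxidase and bd ubiquinol oxidase modules. KEGG content is versioned
#' external data: real analyses should pass their own definitions (TSV via
#' [read_table()] + [module_list()]); the classifier logic only owns the >= 50%
#' completeness rule.
#'
#' @return Named list with elements `cytc_oxidase`, `cbb3_oxidase`,
#'   `bd_oxidase`, each a list of step alternative sets.
#' @export
default_oxidase_modules <- function() {
  list(
    cytc_oxidase = list(c("coxA", "ctaD"), c("coxB", "ctaC"), c("coxC", "ctaE")),
    cbb3_oxidase = list("ccoN", "ccoO", "ccoP"),
    bd_oxidase   = list("cydA", "cydB", "cydX")
  )
}

#' Aerobic-respiration flags for one genome
#'
#' A genome is flagged for each oxidase class whose module is >= 50% complete.
#' Chemolithoautotrophic ammonia-oxidizing archaea (family Nitrosopumilaceae)
#' carry a Complex IV too divergent for ortholog-based module annotation, so
#' membership in an override family marks the genome aerobic regardless of
#' module hits.
#'
#' @param features Character vector of feature ids in the genome.
#' @param modules Named list with elements `cytc_oxidase`, `cbb3_oxidase`,
#'   `bd_oxidase` (each a step list); see [default_oxidase_modules()].
#' @param taxonomy Single lineage string (7 ranks) or `NA`.
#' @param override_families Character vector of family names that force
#'   `taxon_override_aerobic`.
#' @return Named logical vector: `has_cytc_oxidase`, `has_cbb3`, `has_bd`,
#'   `taxon_override_aerobic`.
#' @export
classify_aerobic <- function(features, modules = default_oxidase_modules(),
                             taxonomy = NA_character_,
                             override_families = "Nitrosopumilaceae") {
  needed <- c("cytc_oxidase", "cbb3_oxidase", "bd_oxidase")
  if (!all(needed %in% names(modules))) {
    rlang::abort(paste0("classify_aerobic: missing oxidase module definition(s): ",
                        paste(setdiff(needed, names(modules)), collapse = ", ")),
                 class = "hadalguilds_config_error")
  }
  fam <- if (is.na(taxonomy)) "" else parse_taxonomy(taxonomy)$family
  c(has_cytc_oxidase = module_passes(features, modules$cytc_oxidase),
    has_cbb3         = module_passes(features, modules$cbb3_oxidase),
    has_bd           = module_passes(features, modules$bd_oxidase),
    taxon_override_aerobic = fam %in% override_families)
}

#' Nitrogen-respiration flags for one genome
#'
#' Marker rules for the dissimilatory nitrogen cascade: `napAB` and `nrfAH`
#' and `nirBD` need both subunits; `narGHI` needs at least 2 of narG/narH/narI;
#' `nirKS` and `norBC` need at least 1 subunit; `nosZ` is a single gene. A
#' full denitrifier has a nitrate reductase plus nirK/S, norB/C and nosZ.
#'
#' @param features Character vector of feature ids in the genome.
#' @return Named logical vector of the seven step flags plus
#'   `full_denitrifier`.
#' @export
classify_nitrogen <- function(features) {
  napAB  <- all(c("napA", "napB") %in% features)
  narGHI <- sum(c("narG", "narH", "narI") %in% features) >= 2L
  nrfAH  <- all(c("nrfA", "nrfH") %in% features)
  nirBD  <- all(c("nirB", "nirD") %in% features)
  nirKS  <- any(c("nirK", "nirS") %in% features)
  norBC  <- any(c("norB", "norC") %in% features)
  nosZ   <- "nosZ" %in% features
  c(napAB = napAB, narGHI = narGHI, nrfAH = nrfAH, nirBD = nirBD,
    nirKS = nirKS, norBC = norBC, nosZ = nosZ,
    full_denitrifier = (napAB || narGHI) && nirKS && norBC && nosZ)
}

#' Sulfur-respiration flag (dissimilatory sulfite reductase)
#'
#' By default both subunits (dsrA and dsrB) are required; single-subunit hits
#' in draft genomes are often fragments. The flag records presence of dsrAB,
#' not direction: the enzyme also runs oxidatively in some lineages.
#'
#' @param features Character vector of feature ids in the genome.
#' @param require_both If `FALSE`, one subunit suffices.
#' @return Logical scalar.
#' @export
classify_sulfur <- function(features, require_both = TRUE) {
  if (require_both) {
    all(c("dsrA", "dsrB") %in% features)
  } else {
    any(c("dsrA", "dsrB") %in% features)
  }
}

#' Classify every MAG in a catalog into respiratory guilds
#'
#' Applies the aerobic, nitrogen and sulfur rules to each MAG's gene content,
#' copies the metal-reduction flag (porin-cytochrome homologs) from the flag
#' table, and derives the capability columns:
#' `aerobic` = any oxidase or taxon override; `nitrogen` = any of the seven
#' nitrogen step flags; `fermenter` = none of the four respiratory
#' capabilities (operational definition; such genomes may simply respire via
#' pathways outside the rule set).
#'
#' @param catalog `mag_catalog` tibble.
#' @param gene_table `gene_table` tibble (copy counts; presence is what the
#'   rules use).
#' @param metal_flags `metal_flag_table` tibble; MAGs absent from it get
#'   `metal_resp = FALSE`.
#' @param modules Oxidase module definitions, see [classify_aerobic()].
#' @param override_families Families forcing the aerobic taxon override.
#' @param dsr_require_both Passed to [classify_sulfur()].
#' @return `guild_assignment` tibble, one row per catalog MAG.
#' @export
classify_guilds <- function(catalog, gene_table, metal_flags = NULL,
                            modules = default_oxidase_modules(),
                            override_families = "Nitrosopumilaceae",
                            dsr_require_both = TRUE) {
  catalog <- validate_table(catalog, "mag_catalog")
  gene_table <- validate_table(gene_table, "gene_table")
  orphan <- setdiff(unique(gene_table$mag_id), catalog$mag_id)
  if (length(orphan)) {
    rlang::abort(paste0("classify_guilds: gene_table mag_id(s) not in catalog: ",
                        paste(utils::head(orphan, 3), collapse = ", ")),
                 class = "hadalguilds_validation_error")
  }
  no_genes <- setdiff(catalog$mag_id, unique(gene_table$mag_id))
  if (length(no_genes)) {
    rlang::warn(paste0("classify_guilds: ", length(no_genes),
                       " MAG(s) have no gene annotations; classified from an ",
                       "empty gene set"))
  }
  genes_by_mag <- split(gene_table$feature_id, gene_table$mag_id)
  metal_lookup <- if (is.null(metal_flags)) {
    stats::setNames(logical(0), character(0))
  } else {
    metal_flags <- validate_table(metal_flags, "metal_flag_table")
    stats::setNames(metal_flags$porin_cytochrome_homolog, metal_flags$mag_id)
  }
  fam <- parse_taxonomy(catalog$taxonomy)$family

  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    id <- catalog$mag_id[i]
    f <- genes_by_mag[[id]]
    if (is.null(f)) f <- character(0)
    aer <- classify_aerobic(f, modules, catalog$taxonomy[i], override_families)
    nit <- classify_nitrogen(f)
    dsr <- classify_sulfur(f, require_both = dsr_require_both)
    metal <- isTRUE(unname(metal_lookup[id]))
    aerobic <- unname(aer["has_cytc_oxidase"] || aer["has_cbb3"] ||
                      aer["has_bd"] || aer["taxon_override_aerobic"])
    nitrogen <- unname(any(nit[c("napAB", "narGHI", "nrfAH", "nirBD",
                                 "nirKS", "norBC", "nosZ")]))
    tibble::tibble(
      mag_id = id,
      has_cytc_oxidase = unname(aer["has_cytc_oxidase"]),
      has_cbb3 = unname(aer["has_cbb3"]),
      has_bd = unname(aer["has_bd"]),
      taxon_override_aerobic = unname(aer["taxon_override_aerobic"]),
      napAB = unname(nit["napAB"]), narGHI = unname(nit["narGHI"]),
      nrfAH = unname(nit["nrfAH"]), nirBD = unname(nit["nirBD"]),
      nirKS = unname(nit["nirKS"]), norBC = unname(nit["norBC"]),
      nosZ = unname(nit["nosZ"]),
      full_denitrifier = unname(nit["full_denitrifier"]),
      dsrAB = dsr,
      aerobic = aerobic,
      nitrogen = nitrogen,
      sulfur_resp = dsr,
      metal_resp = metal,
      fermenter = !(aerobic || nitrogen || dsr || metal)
    )
  })
  out <- dplyr::bind_rows(rows)
  validate_table(out, "guild_assignment")
}

#' Count guild-capability overlaps (Venn regions)
#'
#' Partitions the non-fermenter MAGs by their exact capability subset over
#' {aerobic, nitrogen, sulfur_resp, metal_resp}; fermenters (no capability)
#' form their own region, so region counts sum to the number of MAGs.
#'
#' @param assignments `guild_assignment` tibble.
#' @return Tibble with columns `region` (e.g. `"aerobic+nitrogen"`,
#'   `"fermenter"`) and `n`; all 15 nonempty subsets are listed, zeros
#'   included.
#' @export
guild_overlap <- function(assignments) {
  assignments <- validate_table(assignments, "guild_assignment")
  caps <- c("aerobic", "nitrogen", "sulfur_resp", "metal_resp")
  subsets <- unlist(lapply(seq_along(caps), function(k) {
    utils::combn(caps, k, simplify = FALSE)
  }), recursive = FALSE)
  labels <- vapply(subsets, paste, character(1), collapse = "+")
  mag_label <- vapply(seq_len(nrow(assignments)), function(i) {
    present <- caps[unlist(assignments[i, caps])]
    if (length(present) == 0L) "fermenter" else paste(present, collapse = "+")
  }, character(1))
  counts <- table(factor(mag_label, levels = c(labels, "fermenter")))
  stopifnot(sum(counts) == nrow(assignments))
  tibble::tibble(region = names(counts), n = as.integer(counts))
}
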