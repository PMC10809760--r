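#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Schema registry. Each entry: required columns, optional columns, and the
# column types used when reading. The coverage matrix is special-cased (wide
# layout, numeric matrix in memory).
.tbl_schemas <- list(
  mag_catalog = list(
    required = c("mag_id", "taxonomy", "completeness", "redundancy"),
    optional = "genome_size",
    types    = c(mag_id = "c", taxonomy = "c", completeness = "d",
                 redundancy = "d", genome_size = "d")
  ),
  gene_table = list(
    required = c("mag_id", "feature_id", "copies"),
    optional = character(),
    types    = c(mag_id = "c", feature_id = "c", copies = "i")
  ),
  metal_flag_table = list(
    required = c("mag_id", "porin_cytochrome_homolog"),
    optional = character(),
    types    = c(mag_id = "c", porin_cytochrome_homolog = "l")
  ),
  cazyme_table = list(
    required = c("mag_id", "cazyme_family", "copies", "secreted_copies"),
    optional = character(),
    types    = c(mag_id = "c", cazyme_family = "c", copies = "i",
                 secreted_copies = "i")
  ),
  coverage_matrix = list(
    required = "mag_id",
    optional = character(),
    types    = c(mag_id = "c")
  ),
  sample_metadata = list(
    required = c("sample_id", "site_id", "depth_top_cm", "depth_bottom_cm",
                 "water_depth_m", "o2_penetration_cm", "no3_penetration_cm",
                 "sedimentation_rate_mm_yr"),
    optional = "zone",
    types    = c(sample_id = "c", site_id = "c", depth_top_cm = "d",
                 depth_bottom_cm = "d", water_depth_m = "d",
                 o2_penetration_cm = "d", no3_penetration_cm = "d",
                 sedimentation_rate_mm_yr = "d", zone = "c")
  ),
  module_definitions = list(
    required = c("module_id", "step_index", "features"),
    optional = character(),
    types    = c(module_id = "c", step_index = "i", features = "c")
  ),
  guild_assignment = list(
    required = c("mag_id", "aerobic", "nitrogen", "sulfur_resp", "metal_resp",
                 "fermenter"),
    optional = c("has_cytc_oxidase", "has_cbb3", "has_bd",
                 "taxon_override_aerobic", "napAB", "narGHI", "nrfAH", "nirBD",
                 "nirKS", "norBC", "nosZ", "full_denitrifier", "dsrAB"),
    types    = c(mag_id = "c")
  )
)

#' List the tabular schemas understood by the package
#'
#' @return Character vector of schema names accepted by [read_table()] and
#'   [write_table()]. A machine-readable description of every schema ships in
#'   `system.file("extdata", "schemas.json", package = "hadalguilds")`.
#' @export
table_schemas <- function() names(.tbl_schemas)

validation_error <- function(msg) {
  abort(msg, class = "hadalguilds_validation_error")
}

schema_error <- function(msg) {
  abort(msg, class = "hadalguilds_schema_error")
}

#' Read and validate one of the pipeline's input/output tables
#'
#' All tables are UTF-8 TSV with a header row, `"."` as decimal separator and
#' the empty string as missing. The coverage matrix is wide (first column
#' `mag_id`, one numeric column per sample) and is returned as a base matrix;
#' every other schema returns a tibble with row order preserved.
#'
#' @param path Path to a TSV file.
#' @param schema One of [table_schemas()].
#' @return A validated tibble, or a numeric matrix for `"coverage_matrix"`.
#' @seealso [write_table()], [validate_table()]
#' @export
read_table <- function(path, schema) {
  schema <- match.arg(schema, table_schemas())
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (schema == "coverage_matrix") {
    x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"mag_id" %in% names(x)) {
      schema_error("coverage_matrix: missing column 'mag_id'")
    }
    m <- as.matrix(x[setdiff(names(x), "mag_id")])
    storage.mode(m) <- "double"
    rownames(m) <- x$mag_id
    return(validate_table(m, schema))
  }
  sch <- .tbl_schemas[[schema]]
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(sch$required, hdr)
  if (length(missing_cols)) {
    schema_error(paste0(schema, ": missing column(s) ",
                        paste(missing_cols, collapse = ", ")))
  }
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  x <- as_tibble(x)
  keep <- intersect(names(x), c(sch$required, sch$optional))
  x <- x[keep]
  for (cn in names(x)) {
    tp <- if (!is.null(sch$types) && cn %in% names(sch$types)) sch$types[[cn]] else "c"
    x[[cn]] <- switch(tp,
      d = as.numeric(ifelse(x[[cn]] == "", NA, x[[cn]])),
      i = as.integer(ifelse(x[[cn]] == "", NA, x[[cn]])),
      l = as.logical(ifelse(x[[cn]] == "", NA, x[[cn]])),
      ifelse(x[[cn]] == "", NA_character_, x[[cn]])
    )
  }
  validate_table(x, schema)
}

#' Write a validated table to TSV
#'
#' Numeric columns are serialised with 17 significant digits so that
#' `read_table(write_table(x))` round-trips doubles bit-exactly.
#'
#' @param x Table (tibble, data.frame, or matrix for `"coverage_matrix"`).
#' @param path Output path.
#' @param schema One of [table_schemas()].
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, schema) {
  schema <- match.arg(schema, table_schemas())
  x <- validate_table(x, schema)
  if (schema == "coverage_matrix") {
    ch <- matrix(fmt_num(as.vector(x)), nrow = nrow(x), dimnames = dimnames(x))
    df <- data.frame(mag_id = rownames(x), ch,
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(x)
    for (cn in names(df)) {
      if (is.double(df[[cn]])) df[[cn]] <- fmt_num(df[[cn]])
    }
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort(paste0("cannot write ", path, ": ", conditionMessage(ok)))
  invisible(path)
}

fmt_num <- function(v) {
  out <- vapply(v, function(z) {
    if (is.na(z)) "" else sprintf("%.17g", z)
  }, character(1))
  out
}

#' Validate a table against its schema invariants
#'
#' Checks the intra-table invariants (key uniqueness, ranges, label formats,
#' interval consistency). Cross-table key consistency is checked where tables
#' meet, e.g. in [classify_guilds()] and [run_pipeline()].
#'
#' @inheritParams write_table
#' @return The table, invisibly usable (returned unchanged on success).
#' @export
validate_table <- function(x, schema) {
  schema <- match.arg(schema, table_schemas())
  switch(schema,
    mag_catalog      = validate_mag_catalog(x),
    gene_table       = validate_gene_table(x),
    metal_flag_table = validate_metal_flags(x),
    cazyme_table     = validate_cazyme_table(x),
    coverage_matrix  = validate_coverage(x),
    sample_metadata  = validate_sample_metadata(x),
    module_definitions = validate_module_defs(x),
    guild_assignment = validate_guild_assignment(x)
  )
}

need_cols <- function(x, schema) {
  sch <- .tbl_schemas[[schema]]
  missing_cols <- setdiff(sch$required, names(x))
  if (length(missing_cols)) {
    schema_error(paste0(schema, ": missing column(s) ",
                        paste(missing_cols, collapse = ", ")))
  }
}

validate_mag_catalog <- function(x) {
  need_cols(x, "mag_catalog")
  if (anyDuplicated(x$mag_id)) {
    validation_error(paste0("mag_catalog: duplicated mag_id '",
                            x$mag_id[duplicated(x$mag_id)][1], "'"))
  }
  bad <- which(!(x$completeness >= 75 & x$completeness <= 100))
  if (length(bad)) {
    validation_error(paste0("mag_catalog: completeness outside [75, 100] for '",
                            x$mag_id[bad[1]], "' (", x$completeness[bad[1]], ")"))
  }
  bad <- which(!(x$redundancy >= 0 & x$redundancy < 10))
  if (length(bad)) {
    validation_error(paste0("mag_catalog: redundancy outside [0, 10) for '",
                            x$mag_id[bad[1]], "' (", x$redundancy[bad[1]], ")"))
  }
  n_ranks <- lengths(strsplit(paste0(x$taxonomy, ";END"), ";", fixed = TRUE))
  bad <- which(n_ranks != 8L)  # 7 rank slots + sentinel
  if (length(bad)) {
    validation_error(paste0("mag_catalog: taxonomy of '", x$mag_id[bad[1]],
                            "' does not have 7 semicolon-delimited ranks"))
  }
  if ("genome_size" %in% names(x)) {
    bad <- which(!is.na(x$genome_size) & x$genome_size <= 0)
    if (length(bad)) {
      validation_error(paste0("mag_catalog: genome_size <= 0 for '",
                              x$mag_id[bad[1]], "'"))
    }
  }
  as_tibble(x)
}

validate_gene_table <- function(x) {
  need_cols(x, "gene_table")
  key <- paste(x$mag_id, x$feature_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    validation_error(paste0("gene_table: duplicated (mag_id, feature_id) = ('",
                            x$mag_id[d], "', '", x$feature_id[d], "')"))
  }
  bad <- which(!(x$copies >= 1))
  if (length(bad)) {
    validation_error(paste0("gene_table: copies < 1 in row ", bad[1]))
  }
  as_tibble(x)
}

validate_metal_flags <- function(x) {
  need_cols(x, "metal_flag_table")
  if (anyDuplicated(x$mag_id)) {
    validation_error("metal_flag_table: duplicated mag_id")
  }
  if (anyNA(x$porin_cytochrome_homolog)) {
    validation_error("metal_flag_table: porin_cytochrome_homolog must be TRUE/FALSE")
  }
  as_tibble(x)
}

validate_cazyme_table <- function(x) {
  need_cols(x, "cazyme_table")
  if (nrow(x) == 0L) return(as_tibble(x))
  key <- paste(x$mag_id, x$cazyme_family, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    validation_error(paste0("cazyme_table: duplicated (mag_id, family) = ('",
                            x$mag_id[d], "', '", x$cazyme_family[d], "')"))
  }
  bad <- which(!grepl("^(GH|PL|CBM|GT|CE|AA)[0-9]+$", x$cazyme_family))
  if (length(bad)) {
    validation_error(paste0("cazyme_table: malformed family label '",
                            x$cazyme_family[bad[1]], "' in row ", bad[1]))
  }
  bad <- which(!(x$copies >= 1L))
  if (length(bad)) validation_error(paste0("cazyme_table: copies < 1 in row ", bad[1]))
  bad <- which(x$secreted_copies < 0L | x$secreted_copies > x$copies)
  if (length(bad)) {
    validation_error(paste0("cazyme_table: secreted_copies outside [0, copies] in row ",
                            bad[1], " ('", x$mag_id[bad[1]], "', '",
                            x$cazyme_family[bad[1]], "')"))
  }
  as_tibble(x)
}

validate_coverage <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    schema_error("coverage_matrix: expected a numeric matrix with mag_id rownames")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    schema_error("coverage_matrix: row (mag_id) and column (sample_id) names required")
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    validation_error("coverage_matrix: duplicated mag_id or sample_id")
  }
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    validation_error(paste0("coverage_matrix: negative or non-finite coverage at (",
                            rownames(x)[bad[1, 1]], ", ", colnames(x)[bad[1, 2]], ")"))
  }
  x
}

validate_sample_metadata <- function(x) {
  need_cols(x, "sample_metadata")
  if (anyDuplicated(x$sample_id)) {
    validation_error("sample_metadata: duplicated sample_id")
  }
  bad <- which(!(x$depth_top_cm >= 0 & x$depth_bottom_cm > x$depth_top_cm))
  if (length(bad)) {
    validation_error(paste0("sample_metadata: bad depth interval for sample '",
                            x$sample_id[bad[1]], "'"))
  }
  bad <- which(!(x$water_depth_m > 0))
  if (length(bad)) {
    validation_error(paste0("sample_metadata: water_depth_m <= 0 for '",
                            x$sample_id[bad[1]], "'"))
  }
  bad <- which(!(x$o2_penetration_cm > 0))
  if (length(bad)) {
    validation_error(paste0("sample_metadata: o2_penetration_cm <= 0 for '",
                            x$sample_id[bad[1]], "'"))
  }
  bad <- which(!(x$no3_penetration_cm > x$o2_penetration_cm))
  if (length(bad)) {
    validation_error(paste0("sample_metadata: no3_penetration_cm <= o2_penetration_cm",
                            " at site '", x$site_id[bad[1]], "'"))
  }
  bad <- which(!(x$sedimentation_rate_mm_yr > 0))
  if (length(bad)) {
    validation_error(paste0("sample_metadata: sedimentation_rate_mm_yr <= 0 for '",
                            x$sample_id[bad[1]], "'"))
  }
  out_band <- which(x$sedimentation_rate_mm_yr < 0.01 | x$sedimentation_rate_mm_yr > 10)
  if (length(out_band)) {
    warn(paste0("sample_metadata: sedimentation rate outside plausibility band ",
                "(0.01-10 mm/yr) for sample '", x$sample_id[out_band[1]], "'"))
  }
  # non-overlapping intervals within a site (half-open [top, bottom))
  for (s in unique(x$site_id)) {
    xi <- x[x$site_id == s, ]
    o <- order(xi$depth_top_cm)
    if (any(xi$depth_top_cm[o][-1] < xi$depth_bottom_cm[o][-nrow(xi)])) {
      validation_error(paste0("sample_metadata: overlapping depth intervals at site '",
                              s, "'"))
    }
  }
  if ("zone" %in% names(x)) {
    bad <- which(!is.na(x$zone) &
                 !x$zone %in% c("oxic", "nitrogenous", "ferruginous", "transitional"))
    if (length(bad)) {
      validation_error(paste0("sample_metadata: unknown zone label '",
                              x$zone[bad[1]], "'"))
    }
  }
  as_tibble(x)
}

validate_module_defs <- function(x) {
  need_cols(x, "module_definitions")
  if (nrow(x) == 0L) validation_error("module_definitions: at least one step required")
  empty <- which(is.na(x$features) | x$features == "")
  if (length(empty)) {
    validation_error(paste0("module_definitions: empty step in module '",
                            x$module_id[empty[1]], "'"))
  }
  as_tibble(x)
}

validate_guild_assignment <- function(x) {
  need_cols(x, "guild_assignment")
  if (anyDuplicated(x$mag_id)) validation_error("guild_assignment: duplicated mag_id")
  as_tibble(x)
}

#' Convert a long module-definition table into a list of step sets
#'
#' @param x Tibble with columns `module_id`, `step_index`, `features`
#'   (comma-joined alternative feature ids for that step).
#' @return Named list: one element per module, each an ordered list of
#'   character vectors (the alternative features of each step).
#' @export
module_list <- function(x) {
  x <- validate_table(x, "module_definitions")
  out <- lapply(split(x, x$module_id), function(m) {
    m <- m[order(m$step_index), ]
    lapply(strsplit(m$features, ",", fixed = TRUE), trimws)
  })
  out[unique(x$module_id)]
}

#' Parse GTDB-style taxonomy strings
#'
#' Splits 7-rank, semicolon-delimited lineages and strips `d__`-style rank
#' prefixes. Empty ranks are preserved as empty strings.
#'
#' @param taxonomy Character vector of lineage strings.
#' @return Tibble with columns domain, phylum, class, order, family, genus,
#'   species.
#' @export
parse_taxonomy <- function(taxonomy) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus", "species")
  parts <- strsplit(taxonomy, ";", fixed = TRUE)
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- 7L
    p[is.na(p)] <- ""
    sub("^[dpcofgs]__", "", p)
  }, character(7)))
  colnames(m) <- ranks
  as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
}
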