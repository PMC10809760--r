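#' Assign a sediment horizon to a redox zone
#'
#' Zones follow the classical electron-acceptor cascade: the oxic zone ends at
#' the O2 penetration depth, the nitrogenous zone (nitrate/nitrite and Mn
#' respiration) at the NO3 penetration depth, and everything deeper is
#' ferruginous (Fe(III) reduction, porewater Fe2+ accumulation). A horizon is
#' placed by its midpoint `(top + bottom) / 2`; boundaries are half-open, so a
#' midpoint exactly at a penetration depth falls into the deeper zone.
#'
#' @param depth_top_cm,depth_bottom_cm Horizon interval, cm below the sediment
#'   surface, `0 <= top < bottom`.
#' @param o2_penetration_cm,no3_penetration_cm Per-site penetration depths,
#'   cm, `0 < o2 < no3`.
#' @param site_id Optional site label used in error messages.
#' @return Character vector with values `"oxic"`, `"nitrogenous"`,
#'   `"ferruginous"`.
#' @examples
#' assign_zone(0, 1, o2_penetration_cm = 3, no3_penetration_cm = 8)
#' @export
assign_zone <- function(depth_top_cm, depth_bottom_cm,
                        o2_penetration_cm, no3_penetration_cm,
                        site_id = NULL) {
  if (any(!(depth_top_cm >= 0 & depth_bottom_cm > depth_top_cm))) {
    rlang::abort("assign_zone: need 0 <= depth_top_cm < depth_bottom_cm")
  }
  bad <- which(!(o2_penetration_cm > 0 & no3_penetration_cm > o2_penetration_cm))
  if (length(bad)) {
    where <- if (is.null(site_id)) "" else paste0(" at site '", site_id[bad[1]], "'")
    rlang::abort(paste0("assign_zone: need 0 < o2 < no3 penetration depth", where),
                 class = "hadalguilds_validation_error")
  }
  mid <- (depth_top_cm + depth_bottom_cm) / 2
  ifelse(mid < o2_penetration_cm, "oxic",
         ifelse(mid < no3_penetration_cm, "nitrogenous", "ferruginous"))
}

#' Fill the zone column of a sample-metadata table
#'
#' Applies [assign_zone()] per sample using that sample's site-level O2 and
#' NO3 penetration depths. Redox boundaries in real cores can shift by a
#' couple of centimetres; with `boundary_buffer_cm > 0`, samples whose
#' midpoint is within the buffer of either boundary are relabelled
#' `"transitional"` so they can be excluded from per-zone summaries.
#'
#' @param metadata `sample_metadata` tibble (see [read_table()]).
#' @param boundary_buffer_cm Non-negative half-width of the transitional band
#'   around each boundary; default 0 (no transitional labels).
#' @return The metadata with the `zone` column populated.
#' @export
annotate_zones <- function(metadata, boundary_buffer_cm = 0) {
  metadata <- validate_table(metadata, "sample_metadata")
  if (anyNA(metadata$no3_penetration_cm) || anyNA(metadata$o2_penetration_cm)) {
    bad <- which(is.na(metadata$no3_penetration_cm) | is.na(metadata$o2_penetration_cm))[1]
    rlang::abort(paste0("annotate_zones: missing penetration depth at site '",
                        metadata$site_id[bad], "'"),
                 class = "hadalguilds_validation_error")
  }
  zone <- assign_zone(metadata$depth_top_cm, metadata$depth_bottom_cm,
                      metadata$o2_penetration_cm, metadata$no3_penetration_cm,
                      site_id = metadata$site_id)
  if (boundary_buffer_cm > 0) {
    mid <- (metadata$depth_top_cm + metadata$depth_bottom_cm) / 2
    near <- abs(mid - metadata$o2_penetration_cm) < boundary_buffer_cm |
            abs(mid - metadata$no3_penetration_cm) < boundary_buffer_cm
    zone[near] <- "transitional"
  }
  metadata$zone <- zone
  counts <- table(factor(zone, levels = c("oxic", "nitrogenous", "ferruginous",
                                          "transitional")))
  rlang::inform(paste0("zones: ", paste(names(counts), counts, sep = "=",
                                        collapse = ", ")))
  metadata
}
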