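#' Load the spatial study-unit inventory
#'
#' The packaged fixture enumerates the 35 numbered study units of the
#' three Chongqing community sports parks with their space type
#' (fitness-equipment, path, or sports-court space) and subtype
#' (basketball court, plastic runway, ...). Unit-to-park assignment in
#' the fixture is a synthetic stand-in (see the fixture comment); the
#' space-type membership is exact.
#'
#' @param path path to a JSON fixture; defaults to the packaged inventory.
#' @return data.frame with columns `unit_id`, `park`, `space_type`,
#'   `subtype`.
#' @export
load_spatial_units <- function(path = system.file("extdata", "spatial_units.json",
                                                  package = "parkbbn")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  units <- raw$units
  blocks <- raw$park_blocks
  park <- rep(NA_character_, nrow(units))
  for (p in names(blocks)) {
    rng <- unlist(blocks[[p]])
    park[units$unit_id >= rng[1L] & units$unit_id <= rng[2L]] <- p
  }
  units$park <- park
  if (anyDuplicated(units$unit_id))
    stop("duplicate unit_id in unit inventory", call. = FALSE)
  bad <- !units$space_type %in% c("fitness_equipment", "path", "sports_court")
  if (any(bad))
    stop("unknown space_type: ", paste(unique(units$space_type[bad]), collapse = ", "),
         call. = FALSE)
  units[, c("unit_id", "park", "space_type", "subtype")]
}

#' Count study units by space type and park
#'
#' @param units unit inventory data.frame as from [load_spatial_units()].
#' @return list with `total`, `by_space_type`, `by_park`, `by_subtype`.
#' @export
unit_inventory_counts <- function(units) {
  if (!nrow(units)) {
    return(list(total = 0L, by_space_type = integer(0),
                by_park = integer(0), by_subtype = integer(0)))
  }
  if (anyDuplicated(units$unit_id))
    stop("duplicate unit_id in unit inventory", call. = FALSE)
  list(total = nrow(units),
       by_space_type = table(units$space_type),
       by_park = table(units$park),
       by_subtype = table(units$subtype))
}

#' Valid questionnaire tallies per park
#'
#' Counts of valid engagement questionnaires collected in the field
#' campaign, per park.
#'
#' @return named integer vector.
#' @export
questionnaire_tallies <- function() {
  c(Dashuijing = 124L, Huilongwan = 133L, Danlong = 96L)
}
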