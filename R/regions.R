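# Region taxonomy used throughout: the 12 geographic regions of the WHO
# source-apportionment database and their collapse into the four location
# categories used as regression dummies (reference: rest of the world).

#' The 12 region labels
#'
#' Geographic regions to which cities are assigned, following the WHO
#' source-apportionment database convention.
#'
#' @return Character vector of the 12 region names.
#' @export
pm_regions <- function() {
  c(
    "Africa", "Central and Eastern Europe", "East Asia", "Middle East",
    "North America", "Northwestern Europe", "Oceania/Japan",
    "South/Central America", "Southeastern Asia", "Southern Asia",
    "Southwestern Europe", "Western Europe"
  )
}

# Observation frequency of each region in a paper-scale (n = 182) dataset;
# used as the default categorical law of the synthetic generator.
pm_region_counts <- function() {
  stats::setNames(
    c(1L, 3L, 18L, 5L, 57L, 12L, 9L, 12L, 9L, 9L, 39L, 8L),
    pm_regions()
  )
}

pm_loc_levels <- function() {
  c("NA_Oceania_Japan", "NW_W_Europe", "rest_of_Europe", "rest_of_world")
}

#' Collapse a region into its location category
#'
#' North America and Oceania/Japan (which includes Japan as a high-income
#' country with comparable concentrations) form the first category;
#' Northwestern and Western Europe the second; the remaining European
#' regions the third; everything else is the reference "rest of the world".
#'
#' @param region Character vector of region labels from [pm_regions()].
#' @return Factor with levels `NA_Oceania_Japan`, `NW_W_Europe`,
#'   `rest_of_Europe`, `rest_of_world`.
#' @export
region_to_loc_cat <- function(region) {
  bad <- setdiff(unique(region[!is.na(region)]), pm_regions())
  if (length(bad)) {
    pm_stop(sprintf("unknown region label(s): %s", paste(bad, collapse = ", ")),
            "pm_validation_error")
  }
  out <- rep("rest_of_world", length(region))
  out[region %in% c("North America", "Oceania/Japan")] <- "NA_Oceania_Japan"
  out[region %in% c("Northwestern Europe", "Western Europe")] <- "NW_W_Europe"
  out[region %in% c("Central and Eastern Europe", "Southwestern Europe")] <- "rest_of_Europe"
  out[is.na(region)] <- NA_character_
  factor(out, levels = pm_loc_levels())
}

# One representative country per region, for synthetic city generation.
pm_region_countries <- function() {
  list(
    "Africa" = c("Ghana", "Kenya"),
    "Central and Eastern Europe" = c("Poland", "Czechia"),
    "East Asia" = c("China", "South Korea"),
    "Middle East" = c("Iran", "United Arab Emirates"),
    "North America" = c("United States", "Canada"),
    "Northwestern Europe" = c("United Kingdom", "Netherlands"),
    "Oceania/Japan" = c("Australia", "Japan", "New Zealand"),
    "South/Central America" = c("Brazil", "Chile", "Mexico"),
    "Southeastern Asia" = c("Thailand", "Vietnam"),
    "Southern Asia" = c("India", "Pakistan", "Bangladesh"),
    "Southwestern Europe" = c("Spain", "Italy", "Portugal"),
    "Western Europe" = c("France", "Germany", "Switzerland")
  )
}
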