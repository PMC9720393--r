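#' @keywords internal
"_PACKAGE"

SEEDBANK_MODES <- c("RG", "RM", "RC", "RD")
SEEDBANK_GUILDS <- c("grass", "sedge", "broadleaf")

#' Validate and coerce a long-format quadrat survey table
#'
#' A survey is a long-format data frame with one row per (quadrat, species)
#' pair: columns `site`, `mode`, `field`, `quadrat`, `species`, `count`.
#' Species absent from a quadrat may simply be omitted (they count as zero),
#' but every sampled quadrat must appear in at least one row so that quadrat
#' totals are well defined. Sampling geometry (number of elutriated soil
#' parts per quadrat and the area each part represents) is carried as
#' attributes `parts_examined` and `part_area_m2`.
#'
#' @param df data frame with columns site, mode, field, quadrat, species,
#'   count.
#' @param parts_examined number of soil parts per quadrat examined for seeds
#'   (default 3).
#' @param part_area_m2 ground area represented by one examined part, in m^2
#'   (default 0.016).
#' @return the validated data frame, classed `seedbank_survey`, with geometry
#'   attributes attached.
#' @export
as_survey <- function(df, parts_examined = 3, part_area_m2 = 0.016) {
  required <- c("site", "mode", "field", "quadrat", "species", "count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("survey is missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[required]
  df$site <- as.character(df$site)
  df$mode <- as.character(df$mode)
  df$species <- as.character(df$species)
  bad_mode <- setdiff(unique(df$mode), SEEDBANK_MODES)
  if (length(bad_mode) > 0)
    stop("unknown production mode(s): ", paste(bad_mode, collapse = ", "))
  df$field <- as.integer(df$field)
  df$quadrat <- as.integer(df$quadrat)
  df$count <- as.numeric(df$count)
  if (anyNA(df$count)) stop("non-numeric or missing seed count")
  if (any(df$count < 0)) stop("negative seed count")
  if (any(df$count != round(df$count))) stop("seed counts must be integers")
  df$count <- as.integer(df$count)
  dup <- duplicated(df[c("site", "field", "quadrat", "species")])
  if (any(dup))
    stop("duplicated (site, field, quadrat, species) row(s), first at line ",
         which(dup)[1])
  if (!is.numeric(parts_examined) || parts_examined < 1)
    stop("parts_examined must be a positive integer")
  if (!is.numeric(part_area_m2) || part_area_m2 <= 0)
    stop("part_area_m2 must be > 0")
  attr(df, "parts_examined") <- as.integer(parts_examined)
  attr(df, "part_area_m2") <- as.numeric(part_area_m2)
  class(df) <- c("seedbank_survey", "data.frame")
  df
}

#' Read a quadrat survey from CSV
#'
#' Expects a long-format CSV with header columns
#' `site,mode,field,quadrat,species,count`. Species/quadrat pairs not listed
#' are treated as zero counts.
#'
#' @inheritParams as_survey
#' @param path path to a CSV file.
#' @return a validated `seedbank_survey` data frame.
#' @seealso [write_survey()]
#' @export
read_survey <- function(path, parts_examined = 3, part_area_m2 = 0.016) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse survey CSV '", path, "': ",
                             conditionMessage(e))
  )
  as_survey(df, parts_examined = parts_examined, part_area_m2 = part_area_m2)
}

#' Write a quadrat survey to CSV
#'
#' @param survey a `seedbank_survey` data frame (see [as_survey()]).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_survey <- function(survey, path) {
  utils::write.csv(as.data.frame(survey), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Geometry accessors for a survey
#'
#' @param survey a `seedbank_survey` data frame.
#' @return `survey_parts()` the number of examined soil parts per quadrat;
#'   `survey_part_area()` the area (m^2) each part represents.
#' @export
survey_parts <- function(survey) {
  p <- attr(survey, "parts_examined")
  if (is.null(p)) 3L else p
}

#' @rdname survey_parts
#' @export
survey_part_area <- function(survey) {
  a <- attr(survey, "part_area_m2")
  if (is.null(a)) 0.016 else a
}

#' Site practice records from a multi-site organic rice survey
#'
#' Returns the packaged table of the 12 sampling sites of a published survey
#' of organic rice soil weed seed banks in Jiangsu Province: production mode
#' (RG rice-green manure rotation, RM rice monoculture, RC rice-crayfish
#' coculture, RD rice-duck coculture), region, consecutive planting years,
#' rice variety, and annual farming-practice quantities (tillage passes,
#' irrigation in 10^3 m^3/ha, organic fertilizer and green manure in
#' 10^3 kg/ha, juvenile crayfish in kg/ha, ducklings per ha, hand weeding in
#' h/ha).
#'
#' @return data frame with 12 rows, one per sampling site.
#' @export
jiangsu_practices <- function() {
  path <- system.file("extdata", "jiangsu_practices.csv",
                      package = "seedbankr", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_practices(df)
  df
}

#' Weed species pool and occurrence classes from a multi-site survey
#'
#' Returns the packaged table of the 61 weed species recorded in the soil
#' seed banks of four organic rice production modes, with the functional
#' guild of each species (grass, sedge or broadleaf) and, per mode, the
#' number of sampling fields (0-3) in which the species occurred.
#' `rice_associated` is NA throughout: the source table does not identify
#' which species are rice-associated.
#'
#' @return data frame with 61 rows and columns `species_id`, `latin_name`,
#'   `guild`, `rice_associated`, `RG`, `RM`, `RC`, `RD`.
#' @export
jiangsu_occurrence <- function() {
  path <- system.file("extdata", "jiangsu_occurrence.csv",
                      package = "seedbankr", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "NA")
  df$rice_associated <- as.logical(df$rice_associated)
  validate_species_pool(df)
  occ <- as.matrix(df[SEEDBANK_MODES])
  if (any(occ < 0 | occ > 3)) stop("occurrence classes must be in 0..3")
  if (any(rowSums(occ) == 0)) stop("species with no occurrence in any mode")
  df
}

validate_species_pool <- function(pool) {
  required <- c("species_id", "guild")
  missing_cols <- setdiff(required, names(pool))
  if (length(missing_cols) > 0)
    stop("species pool is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(pool$species_id))
    stop("duplicated species_id in species pool")
  bad <- setdiff(unique(pool$guild), SEEDBANK_GUILDS)
  if (length(bad) > 0)
    stop("unknown guild(s): ", paste(bad, collapse = ", "))
  invisible(pool)
}

validate_practices <- function(practices) {
  required <- c("site_id", "mode", "consecutive_years", "rice_variety",
                "tillage_per_year", "irrigation_1e3m3_ha",
                "organic_fertilizer_1e3kg_ha", "green_manure_1e3kg_ha",
                "crayfish_kg_ha", "duckling_per_ha", "hand_weeding_h_ha")
  missing_cols <- setdiff(required, names(practices))
  if (length(missing_cols) > 0)
    stop("practices table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(practices$site_id))
    stop("one practice record per site required")
  bad <- setdiff(unique(practices$mode), SEEDBANK_MODES)
  if (length(bad) > 0)
    stop("unknown production mode(s): ", paste(bad, collapse = ", "))
  num <- practices[required[-(1:2)][-2]]
  num <- num[vapply(num, is.numeric, logical(1))]
  if (any(unlist(num) < 0, na.rm = TRUE))
    stop("practice quantities must be non-negative")
  if (any(practices$consecutive_years < 1))
    stop("consecutive_years must be >= 1")
  invisible(practices)
}

#' Numeric practice covariates used as community drivers
#'
#' The seven annual-practice columns (tillage, irrigation, organic
#' fertilizer, green manure, crayfish, duckling, hand weeding), in the order
#' used by [survey_design()]'s `covariate_effect` matrix.
#'
#' @return character vector of column names.
#' @export
practice_covariates <- function() {
  c("tillage_per_year", "irrigation_1e3m3_ha", "organic_fertilizer_1e3kg_ha",
    "green_manure_1e3kg_ha", "crayfish_kg_ha", "duckling_per_ha",
    "hand_weeding_h_ha")
}
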