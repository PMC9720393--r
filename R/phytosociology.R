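#' Convert seed counts to areal seed density
#'
#' A quadrat's seed count comes from `parts_examined` elutriated soil parts,
#' each representing `part_area_m2` of ground, so
#' density = count / (parts_examined * part_area_m2). At the default
#' geometry (3 parts of 0.016 m^2) the area basis is 0.048 m^2 per quadrat.
#'
#' @param count non-negative seed count(s).
#' @param parts_examined number of soil parts examined per quadrat.
#' @param part_area_m2 area represented by one part, m^2.
#' @return seed density in seeds per m^2.
#' @export
counts_to_density <- function(count, parts_examined = 3,
                              part_area_m2 = 0.016) {
  if (parts_examined < 1) stop("parts_examined must be >= 1")
  if (part_area_m2 <= 0) stop("part_area_m2 must be > 0")
  if (any(count < 0)) stop("negative seed count")
  count / (parts_examined * part_area_m2)
}

#' Phytosociological parameters and importance value per stratum
#'
#' For each stratum (by default each production mode) computes, per species
#' observed in the stratum:
#' absolute frequency AF (fraction of quadrats where present), absolute
#' density AD (total seeds / total sampled area, seeds per m^2), absolute
#' abundance AA (total seeds / number of quadrats containing the species),
#' their relative forms RF, RD, RA (each normalized to sum to 1 over the
#' stratum's species) and the importance value IV = RF + RD + RA (so IV
#' sums to 3 over species). The total sampled area of a stratum is
#' n_quadrats x parts_examined x part_area_m2, consistent with
#' [counts_to_density()]. Species never observed in a stratum are excluded
#' from its table.
#'
#' @param survey a `seedbank_survey` data frame (see [as_survey()]).
#' @param by character vector of survey columns defining strata (default
#'   `"mode"`; use `c("site", "field")` for the per-field tables that feed
#'   ordination).
#' @return data frame with one row per (stratum, species):
#'   columns `stratum`, the `by` columns, `species`, `AF`, `RF`, `AD`,
#'   `RD`, `AA`, `RA`, `IV`.
#' @export
phyto_table <- function(survey, by = "mode") {
  if (!all(by %in% names(survey)))
    stop("unknown stratum column(s): ",
         paste(setdiff(by, names(survey)), collapse = ", "))
  parts <- survey_parts(survey)
  area <- survey_part_area(survey)
  strat_key <- interaction(survey[by], drop = TRUE, sep = ":")
  out <- lapply(levels(strat_key), function(lv) {
    sub <- survey[strat_key == lv, , drop = FALSE]
    tab <- phyto_one_stratum(sub, parts, area)
    if (is.null(tab)) stop("stratum '", lv, "' has no seeds; ",
                           "relative parameters are undefined")
    meta <- unique(sub[by])
    cbind(stratum = lv, meta[rep(1, nrow(tab)), , drop = FALSE], tab,
          row.names = NULL)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

phyto_one_stratum <- function(sub, parts, area) {
  quad <- interaction(sub$site, sub$field, sub$quadrat, drop = TRUE)
  n_quadrats <- nlevels(quad)
  present <- sub$count > 0
  if (!any(present)) return(NULL)
  sp <- factor(sub$species[present])
  totals <- tapply(sub$count[present], sp, sum)
  occupied <- tapply(quad[present], sp,
                     function(q) length(unique(q)))
  AF <- occupied / n_quadrats
  AD <- totals / (n_quadrats * parts * area)
  AA <- totals / occupied
  data.frame(
    species = names(totals),
    AF = as.numeric(AF),
    RF = as.numeric(AF / sum(AF)),
    AD = as.numeric(AD),
    RD = as.numeric(AD / sum(AD)),
    AA = as.numeric(AA),
    RA = as.numeric(AA / sum(AA)),
    IV = as.numeric(AF / sum(AF) + AD / sum(AD) + AA / sum(AA)),
    stringsAsFactors = FALSE
  )
}

#' Guild composition of a phytosociology table
#'
#' Shares of the total importance value held by each functional guild
#' (grass, sedge, broadleaf), per stratum, as percentages summing to 100.
#'
#' @param tab output of [phyto_table()].
#' @param pool species pool with `species_id` and `guild` covering every
#'   species in `tab`.
#' @return data frame with columns `stratum`, `guild`, `iv`, `pct`.
#' @export
guild_composition <- function(tab, pool) {
  validate_species_pool(pool)
  guild <- pool$guild[match(tab$species, pool$species_id)]
  if (anyNA(guild))
    stop("species without guild: ",
         paste(unique(tab$species[is.na(guild)]), collapse = ", "))
  out <- lapply(unique(tab$stratum), function(lv) {
    i <- tab$stratum == lv
    iv <- tapply(tab$IV[i], factor(guild[i], levels = SEEDBANK_GUILDS), sum)
    iv[is.na(iv)] <- 0
    data.frame(stratum = lv, guild = SEEDBANK_GUILDS,
               iv = as.numeric(iv),
               pct = 100 * as.numeric(iv) / sum(iv),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Guild importance-value shares per field
#'
#' Convenience wrapper: per-field phytosociology tables reduced to one row
#' per field with the percentage of total IV per guild; the response table
#' used for boosted-tree driver attribution.
#'
#' @param survey a `seedbank_survey`.
#' @param pool species pool with guilds.
#' @param by stratum columns (default per field).
#' @return data frame with the `by` columns, `mode` and one percentage
#'   column per guild.
#' @export
guild_shares <- function(survey, pool, by = c("site", "field")) {
  tab <- phyto_table(survey, by = by)
  comp <- guild_composition(tab, pool)
  wide <- stats::reshape(comp[c("stratum", "guild", "pct")],
                         idvar = "stratum", timevar = "guild",
                         direction = "wide")
  names(wide) <- sub("^pct\\.", "", names(wide))
  meta <- unique(tab[c("stratum", by, intersect("mode", names(tab)))])
  if (!"mode" %in% names(meta) && "mode" %in% names(survey)) {
    mode_of <- unique(survey[c(by[1], "mode")])
    meta$mode <- mode_of$mode[match(meta[[by[1]]], mode_of[[by[1]]])]
  }
  res <- merge(meta, wide, by = "stratum", sort = FALSE)
  rownames(res) <- NULL
  res
}

#' Rank dominant species by importance value
#'
#' @param tab a single-stratum slice of [phyto_table()] output (or any data
#'   frame with `species` and `IV`).
#' @param k number of species to return (default 10); if larger than the
#'   species count, all species are returned.
#' @return data frame of the top-`k` species sorted by decreasing IV, ties
#'   broken lexicographically by species id.
#' @export
rank_dominants <- function(tab, k = 10) {
  if (k < 1) stop("k must be >= 1")
  ord <- order(-tab$IV, tab$species)
  res <- tab[ord, , drop = FALSE][seq_len(min(k, nrow(tab))), , drop = FALSE]
  rownames(res) <- NULL
  res
}
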