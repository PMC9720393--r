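#' Simulation design for a synthetic seed bank survey
#'
#' Describes a multi-site quadrat survey of the four organic rice production
#' modes (RG, RM, RC, RD): per mode, `sites_per_mode` sites; per site, three
#' non-adjacent fields; per field, nine 1 m^2 quadrats laid out by the
#' inverted-"W" 9-point scheme (quadrats are treated as exchangeable; no
#' spatial autocorrelation is modelled). Seed counts per quadrat arise from
#' an elutriated subsample: `parts_examined` soil parts each representing
#' `part_area_m2` of ground.
#'
#' Community structure: each site's expected guild shares are
#' `softmax(log(mode_guild_profile) + t(covariate_effect) %*% z + site noise)`
#' where `z` are the site's standardized practice covariates. Within a
#' guild, the species that are "active" at a site (a richness that grows
#' with consecutive planting years, `base_richness` +
#' `richness_per_year * (years - min(year_range))`) follow a
#' dominant-plus-rare-tail abundance model: the guild's top species holds a
#' fixed `head_share` of the guild mass and the rest is spread over the
#' remaining active species with geometric rank weights
#' `geometric_ratio^rank` jittered by Gamma(`dirichlet_alpha`) multipliers.
#' Because added richness feeds only the rare tail, the model yields the
#' year-linked diversity gradient (Simpson diversity rising, evenness and
#' ecological dominance falling with years). Counts per
#' quadrat and species are negative binomial (gamma-Poisson) with dispersion
#' `overdispersion_k` around mean = density x sampled area.
#'
#' @param sites_per_mode sites per production mode (default 3, the study
#'   scale: 12 sites).
#' @param fields_per_site fields per site (default 3).
#' @param quadrats_per_field quadrats per field (default 9).
#' @param parts_examined,part_area_m2 sampling geometry (defaults 3 and
#'   0.016 m^2, i.e. 0.048 m^2 examined per quadrat).
#' @param species_pool data frame with `species_id` and `guild`; defaults to
#'   the packaged 61-species pool ([jiangsu_occurrence()]).
#' @param mode_guild_profile 4 x 3 matrix of expected guild shares per mode
#'   (rows RG, RM, RC, RD; columns grass, sedge, broadleaf; rows sum to 1).
#' @param covariate_effect 7 x 3 matrix linking standardized practice
#'   covariates (rows, order [practice_covariates()]) to guild log-shares.
#' @param site_sd SD of Gaussian site effects on guild log-shares.
#' @param density_site_sd,density_field_sd SDs of mean-one lognormal
#'   multipliers on total density at site and field level.
#' @param overdispersion_k negative binomial size parameter (k > 0; larger
#'   is closer to Poisson).
#' @param mean_total_density expected total seed density, seeds per m^2.
#' @param dirichlet_alpha shape of the Gamma jitter on within-guild species
#'   weights.
#' @param geometric_ratio ratio of the geometric rank weights in (0, 1).
#' @param head_share fraction of each guild's abundance held by its
#'   dominant species, in (0, 1); the remainder is spread over the
#'   geometric rare tail.
#' @param base_richness active species at the youngest planting age.
#' @param richness_per_year additional active species per consecutive
#'   planting year.
#' @param year_range integer vector of consecutive planting years to draw
#'   from (default 3:10).
#' @return a `seedbank_design` list.
#' @export
survey_design <- function(sites_per_mode = 3,
                          fields_per_site = 3,
                          quadrats_per_field = 9,
                          parts_examined = 3,
                          part_area_m2 = 0.016,
                          species_pool = NULL,
                          mode_guild_profile = default_guild_profile(),
                          covariate_effect = default_covariate_effect(),
                          site_sd = 0.25,
                          density_site_sd = 0.3,
                          density_field_sd = 0.15,
                          overdispersion_k = 5,
                          mean_total_density = 10000,
                          dirichlet_alpha = 0.5,
                          geometric_ratio = 0.9,
                          head_share = 0.4,
                          base_richness = 12,
                          richness_per_year = 3,
                          year_range = 3:10) {
  if (is.null(species_pool)) species_pool <- jiangsu_occurrence()
  validate_species_pool(species_pool)
  mode_guild_profile <- as.matrix(mode_guild_profile)
  if (!identical(dim(mode_guild_profile), c(4L, 3L)))
    stop("mode_guild_profile must be 4 modes x 3 guilds")
  if (any(mode_guild_profile <= 0) ||
      any(abs(rowSums(mode_guild_profile) - 1) > 1e-8))
    stop("mode_guild_profile rows must be positive and sum to 1")
  covariate_effect <- as.matrix(covariate_effect)
  if (!identical(dim(covariate_effect),
                 c(length(practice_covariates()), 3L)))
    stop("covariate_effect must be 7 covariates x 3 guilds")
  if (sites_per_mode < 0 || fields_per_site < 1 || quadrats_per_field < 1)
    stop("invalid design dimensions")
  if (overdispersion_k <= 0) stop("overdispersion_k must be > 0")
  if (mean_total_density < 0) stop("mean_total_density must be >= 0")
  if (geometric_ratio <= 0 || geometric_ratio >= 1)
    stop("geometric_ratio must be in (0, 1)")
  if (dirichlet_alpha <= 0) stop("dirichlet_alpha must be > 0")
  if (head_share <= 0 || head_share >= 1)
    stop("head_share must be in (0, 1)")
  design <- list(
    sites_per_mode = as.integer(sites_per_mode),
    fields_per_site = as.integer(fields_per_site),
    quadrats_per_field = as.integer(quadrats_per_field),
    parts_examined = as.integer(parts_examined),
    part_area_m2 = part_area_m2,
    species_pool = species_pool,
    mode_guild_profile = mode_guild_profile,
    covariate_effect = covariate_effect,
    site_sd = site_sd,
    density_site_sd = density_site_sd,
    density_field_sd = density_field_sd,
    overdispersion_k = overdispersion_k,
    mean_total_density = mean_total_density,
    dirichlet_alpha = dirichlet_alpha,
    geometric_ratio = geometric_ratio,
    head_share = head_share,
    base_richness = base_richness,
    richness_per_year = richness_per_year,
    year_range = as.integer(year_range)
  )
  class(design) <- "seedbank_design"
  design
}

#' Default per-mode expected guild shares
#'
#' Calibrated to the guild importance-value shares reported for the four
#' production modes (RG dominated by broadleaf weeds, RC by sedges, RD by
#' grasses, RM mixed with a broadleaf plurality).
#'
#' @return 4 x 3 matrix, rows RG/RM/RC/RD, columns grass/sedge/broadleaf.
#' @export
default_guild_profile <- function() {
  m <- rbind(
    RG = c(0.125, 0.128, 0.747),
    RM = c(0.280, 0.290, 0.430),
    RC = c(0.205, 0.465, 0.330),
    RD = c(0.470, 0.141, 0.389)
  )
  colnames(m) <- SEEDBANK_GUILDS
  m / rowSums(m)
}

#' Default covariate-to-guild effects
#'
#' Standardized-covariate effects on guild log-shares, largest for organic
#' fertilizer, then irrigation, then hand weeding, mirroring the relative
#' driver importance reported for these systems.
#'
#' @return 7 x 3 matrix, rows [practice_covariates()], columns guilds.
#' @export
default_covariate_effect <- function() {
  m <- rbind(
    tillage_per_year            = c( 0.05, -0.05,  0.00),
    irrigation_1e3m3_ha         = c( 0.10,  0.35, -0.45),
    organic_fertilizer_1e3kg_ha = c(-0.20, -0.30,  0.50),
    green_manure_1e3kg_ha       = c(-0.05, -0.05,  0.10),
    crayfish_kg_ha              = c(-0.05,  0.15, -0.10),
    duckling_per_ha             = c( 0.15, -0.10, -0.05),
    hand_weeding_h_ha           = c(-0.25,  0.10,  0.15)
  )
  colnames(m) <- SEEDBANK_GUILDS
  m
}

# Mode-typical practice baselines and site-to-site SDs used by
# simulate_practices(); means follow the published per-mode values.
mode_practice_baseline <- function() {
  mean_tab <- rbind(
    RG = c(4, 5.53,  6.00, 27.9,   0,   0, 42.0),
    RM = c(3, 5.57, 12.93,  0.0,   0,   0, 42.5),
    RC = c(3, 7.83,  5.40,  0.0, 450,   0, 20.7),
    RD = c(3, 6.30,  6.03,  0.0,   0, 255, 22.7)
  )
  sd_tab <- rbind(
    RG = c(0, 0.2, 0.4, 1.6,  0,  0, 1.5),
    RM = c(0, 0.2, 0.4, 0.0,  0,  0, 1.5),
    RC = c(0, 0.2, 0.4, 0.0, 25,  0, 1.5),
    RD = c(0, 0.2, 0.4, 0.0,  0, 15, 1.5)
  )
  colnames(mean_tab) <- colnames(sd_tab) <- practice_covariates()
  list(mean = mean_tab, sd = sd_tab)
}

#' Simulate site practice records
#'
#' Draws one practice record per synthetic site with mode-typical covariate
#' means (RM fertilizer roughly twice the other modes, RC/RD irrigation
#' elevated, RC/RD hand weeding roughly halved), Gaussian site noise
#' truncated at zero, consecutive planting years uniform on
#' `design$year_range`, and one of the two rice varieties.
#'
#' @param design a `seedbank_design` (see [survey_design()]).
#' @param seed integer seed for reproducibility.
#' @return data frame of practice records (one row per site), with `region`
#'   cycling north/middle/south within each mode.
#' @export
simulate_practices <- function(design, seed = NULL) {
  if (!inherits(design, "seedbank_design")) stop("invalid design")
  if (!is.null(seed)) set.seed(seed)
  nspm <- design$sites_per_mode
  base <- mode_practice_baseline()
  cov_names <- practice_covariates()
  out <- vector("list", 4 * max(nspm, 0))
  regions <- c("north", "middle", "south")
  idx <- 0
  for (mode in SEEDBANK_MODES) {
    for (i in seq_len(nspm)) {
      mu <- base$mean[mode, ]
      sdv <- base$sd[mode, ]
      vals <- pmax(0, stats::rnorm(length(mu), mu, sdv))
      vals[sdv == 0] <- mu[sdv == 0]
      rec <- as.list(vals)
      names(rec) <- cov_names
      idx <- idx + 1
      out[[idx]] <- data.frame(
        site_id = sprintf("%s%02d", mode, i),
        mode = mode,
        region = regions[(i - 1) %% 3 + 1],
        consecutive_years = sample(design$year_range, 1),
        rice_variety = sample(c("Nanjing9108", "Nanjing46"), 1,
                              prob = c(2, 1)),
        rec,
        stringsAsFactors = FALSE
      )
    }
  }
  if (idx == 0) {
    df <- data.frame(site_id = character(), mode = character(),
                     region = character(), consecutive_years = integer(),
                     rice_variety = character())
    for (nm in cov_names) df[[nm]] <- numeric()
    return(df)
  }
  res <- do.call(rbind, out)
  res$tillage_per_year <- as.integer(round(res$tillage_per_year))
  rownames(res) <- NULL
  res
}

#' Simulate a quadrat seed bank survey
#'
#' Generates per-quadrat seed counts for every site in `practices` under the
#' community model described in [survey_design()], and returns the
#' ground-truth parameters (guild shares, expected species densities,
#' site/field multipliers) used to generate them, for recovery tests.
#'
#' @param design a `seedbank_design`.
#' @param practices practice records covering every simulated site (e.g.
#'   from [simulate_practices()]); `consecutive_years` drives the active
#'   species richness.
#' @param seed integer seed.
#' @return list with `survey` (a `seedbank_survey` data frame) and `truth`
#'   (per-site guild shares and expected species densities in seeds per
#'   m^2).
#' @export
simulate_survey <- function(design, practices, seed = NULL) {
  if (!inherits(design, "seedbank_design")) stop("invalid design")
  validate_practices(practices)
  if (!is.null(seed)) set.seed(seed)
  pool <- design$species_pool
  n_sp <- nrow(pool)
  cov_names <- practice_covariates()
  Z <- as.matrix(practices[cov_names])
  Z <- apply(Z, 2, function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  if (nrow(practices) == 1) Z <- matrix(0, 1, length(cov_names))
  guild_sizes <- table(factor(pool$guild, levels = SEEDBANK_GUILDS))
  min_year <- min(design$year_range)
  rows <- vector("list", nrow(practices))
  truth_sites <- vector("list", nrow(practices))
  for (s in seq_len(nrow(practices))) {
    site <- practices$site_id[s]
    mode <- practices$mode[s]
    years <- practices$consecutive_years[s]
    eta <- log(design$mode_guild_profile[mode, ]) +
      drop(crossprod(design$covariate_effect, Z[s, ])) +
      stats::rnorm(3, 0, design$site_sd)
    guild_share <- exp(eta - max(eta))
    guild_share <- guild_share / sum(guild_share)
    s_active <- min(n_sp, max(3, round(design$base_richness +
      design$richness_per_year * (years - min_year))))
    w <- numeric(n_sp)
    for (g in SEEDBANK_GUILDS) {
      g_idx <- which(pool$guild == g)
      n_g <- length(g_idx)
      if (n_g == 0 || guild_share[g] == 0) next
      n_act <- max(1, min(n_g, round(s_active * n_g / n_sp)))
      ranked <- sample(g_idx)  # site-specific dominance order
      act <- ranked[seq_len(n_act)]
      if (n_act == 1) {
        wg <- 1
      } else {
        # fixed head share for the guild dominant; the growing active
        # richness feeds only the geometric rare tail, so within-guild
        # evenness falls (and Simpson diversity rises) with richness
        tail_w <- design$geometric_ratio^(seq_len(n_act - 1) - 1) *
          stats::rgamma(n_act - 1, shape = design$dirichlet_alpha,
                        rate = design$dirichlet_alpha)
        wg <- c(design$head_share,
                (1 - design$head_share) * tail_w / sum(tail_w))
      }
      w[act] <- guild_share[g] * wg
    }
    w <- w / sum(w)
    site_mult <- exp(stats::rnorm(1, 0, design$density_site_sd) -
                       design$density_site_sd^2 / 2)
    dens <- design$mean_total_density * site_mult * w
    truth_sites[[s]] <- list(site_id = site, mode = mode,
                             guild_share = guild_share,
                             site_multiplier = site_mult,
                             expected_density = stats::setNames(dens,
                                                                pool$species_id))
    area <- design$parts_examined * design$part_area_m2
    site_rows <- vector("list", design$fields_per_site)
    for (f in seq_len(design$fields_per_site)) {
      field_mult <- exp(stats::rnorm(1, 0, design$density_field_sd) -
                          design$density_field_sd^2 / 2)
      mu <- dens * field_mult * area
      nq <- design$quadrats_per_field
      counts <- matrix(stats::rnbinom(n_sp * nq,
                                      size = design$overdispersion_k,
                                      mu = rep(mu, nq)), nrow = n_sp)
      keep <- which(counts > 0, arr.ind = TRUE)
      if (nrow(keep) > 0) {
        qdf <- data.frame(
          site = site, mode = mode, field = f,
          quadrat = keep[, 2], species = pool$species_id[keep[, 1]],
          count = counts[keep], stringsAsFactors = FALSE
        )
      } else {
        qdf <- NULL
      }
      # quadrats with no seeds at all still need a row (count 0)
      empty_q <- setdiff(seq_len(nq), unique(keep[, 2]))
      if (length(empty_q) > 0) {
        qdf <- rbind(qdf, data.frame(
          site = site, mode = mode, field = f, quadrat = empty_q,
          species = pool$species_id[1], count = 0L,
          stringsAsFactors = FALSE
        ))
      }
      site_rows[[f]] <- qdf
    }
    rows[[s]] <- do.call(rbind, site_rows)
  }
  survey <- do.call(rbind, rows)
  if (is.null(survey) || nrow(survey) == 0)
    stop("empty design: no sites to simulate")
  survey <- survey[order(survey$site, survey$field, survey$quadrat,
                         survey$species), ]
  rownames(survey) <- NULL
  survey <- as_survey(survey, parts_examined = design$parts_examined,
                      part_area_m2 = design$part_area_m2)
  list(survey = survey, truth = truth_sites)
}

#' Simulate practices and survey in one call
#'
#' Convenience wrapper: draws practice records, then the survey conditioned
#' on them, fanning `seed` out to both stages.
#'
#' @inheritParams simulate_survey
#' @param seed integer seed.
#' @return list with `practices`, `survey`, `truth`.
#' @export
simulate_seedbank <- function(design = survey_design(), seed = NULL) {
  practices <- simulate_practices(design, seed = child_seed(seed, 1))
  if (nrow(practices) == 0) stop("empty design: no sites to simulate")
  sim <- simulate_survey(design, practices, seed = child_seed(seed, 2))
  list(practices = practices, survey = sim$survey, truth = sim$truth)
}

# Deterministic per-stage child seeds from one global seed (kept < 2^31).
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 97 + stage * 1000003) %% 2147483629)
}
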