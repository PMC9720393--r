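#' Consecutive-planting-year classes
#'
#' Groups consecutive planting years into the three classes used for trend
#' comparisons: fewer than 5 years, 5 to 7 years, and 8 or more years.
#'
#' @param years positive integer vector of consecutive planting years.
#' @return ordered factor with levels `"<5"`, `"5-7"`, `">=8"`.
#' @export
year_class <- function(years) {
  if (any(years < 1) || any(years != round(years)))
    stop("years must be positive integers")
  cut(years, breaks = c(0, 4.5, 7.5, Inf),
      labels = c("<5", "5-7", ">=8"), ordered_result = TRUE)
}

#' One-way ANOVA with LSD post-hoc letters
#'
#' Fits a one-way ANOVA of (optionally log(x+1)-transformed) values on
#' class labels, reports the F test, Shapiro-Wilk normality and Levene
#' homoscedasticity diagnostics on the analysis scale, all pairwise least
#' significant difference (LSD) t tests on the pooled ANOVA mean square
#' error, and a compact letter display (insert-and-absorb; letters
#' assigned from the highest class mean downwards). LSD comparisons are
#' reported unconditionally, whether or not the overall F test is
#' significant.
#'
#' @param values numeric response.
#' @param classes factor of class labels (>= 2 non-empty classes, each with
#'   >= 2 observations).
#' @param alpha significance level for the letters (default 0.05).
#' @param transform `"none"` or `"log1p"` (applied before all testing).
#' @return list of class `seedbank_trend`: `table` (per-class n, mean, sd
#'   on the analysis scale, raw mean, letter), `F`, `df`, `p_value`,
#'   `shapiro_p`, `levene_p`, `lsd_p` (pairwise matrix), `transform`,
#'   `alpha`.
#' @export
anova_lsd <- function(values, classes, alpha = 0.05,
                      transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  ok <- !is.na(values) & !is.na(classes)
  values <- values[ok]
  classes <- droplevels(factor(classes[ok]))
  if (nlevels(classes) < 2) stop("need at least 2 non-empty classes")
  sizes <- table(classes)
  if (any(sizes < 2))
    stop("class(es) with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  y <- if (transform == "log1p") log1p(values) else values
  if (stats::var(y) == 0) {
    # no variation at all: F is 0 by convention, every class shares a letter
    lv <- levels(classes)
    tab <- data.frame(class = lv, n = as.integer(sizes),
                      mean = as.numeric(tapply(y, classes, mean)),
                      sd = 0,
                      raw_mean = as.numeric(tapply(values, classes, mean)),
                      letter = "a", stringsAsFactors = FALSE)
    k <- length(lv)
    pmat <- matrix(1, k, k, dimnames = list(lv, lv))
    diag(pmat) <- NA_real_
    return(structure(list(table = tab, F = 0,
                          df = c(between = k - 1L,
                                 within = length(y) - k),
                          p_value = 1, shapiro_p = NA_real_,
                          levene_p = NA_real_, lsd_p = pmat,
                          transform = transform, alpha = alpha),
                     class = "seedbank_trend"))
  }
  fit <- stats::aov(y ~ classes)
  at <- stats::anova(fit)
  f_stat <- at[["F value"]][1]
  p_val <- at[["Pr(>F)"]][1]
  df_res <- at[["Df"]][2]
  mse <- at[["Mean Sq"]][2]
  res <- stats::residuals(fit)
  shapiro_p <- tryCatch(stats::shapiro.test(res)$p.value,
                        error = function(e) NA_real_)
  levene_p <- tryCatch(
    car::leveneTest(y ~ classes, center = "mean")[["Pr(>F)"]][1],
    error = function(e) NA_real_)
  lv <- levels(classes)
  means <- tapply(y, classes, mean)
  sds <- tapply(y, classes, stats::sd)
  raw_means <- tapply(values, classes, mean)
  ns <- as.integer(sizes)
  k <- length(lv)
  pmat <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (mse <= 0) {
        pmat[i, j] <- pmat[j, i] <-
          if (means[i] == means[j]) 1 else 0
        next
      }
      se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      tval <- (means[i] - means[j]) / se
      pmat[i, j] <- pmat[j, i] <- 2 * stats::pt(-abs(tval), df_res)
    }
  }
  letters_vec <- compact_letters(means, pmat, alpha)
  tab <- data.frame(class = lv, n = ns, mean = as.numeric(means),
                    sd = as.numeric(sds), raw_mean = as.numeric(raw_means),
                    letter = letters_vec, stringsAsFactors = FALSE)
  structure(list(table = tab, F = f_stat,
                 df = c(between = k - 1L, within = df_res),
                 p_value = p_val, shapiro_p = shapiro_p,
                 levene_p = levene_p, lsd_p = pmat,
                 transform = transform, alpha = alpha),
            class = "seedbank_trend")
}

# Insert-and-absorb compact letter display. `sig[i, j]` TRUE when classes
# differ at alpha; classes processed from the highest mean down, letters
# assigned so that classes share a letter iff not significantly different.
compact_letters <- function(means, pmat, alpha) {
  k <- length(means)
  ord <- order(-means)
  sig <- pmat < alpha
  sig[is.na(sig)] <- FALSE
  groups <- list(ord[1])
  if (k > 1) {
    for (pos in 2:k) {
      i <- ord[pos]
      placed <- FALSE
      for (g in seq_along(groups)) {
        if (!any(sig[i, groups[[g]]])) {
          groups[[g]] <- c(groups[[g]], i)
          placed <- TRUE
        }
      }
      if (!placed) {
        newg <- i
        for (pos2 in (pos - 1):1) {
          j <- ord[pos2]
          if (!any(sig[j, newg])) newg <- c(newg, j)
        }
        groups <- c(groups, list(newg))
      }
    }
  }
  # absorb groups fully contained in another
  keep <- rep(TRUE, length(groups))
  for (a in seq_along(groups)) {
    for (b in seq_along(groups)) {
      if (a != b && keep[a] && keep[b] &&
          all(groups[[a]] %in% groups[[b]])) keep[a] <- FALSE
    }
  }
  groups <- groups[keep]
  first_rank <- vapply(groups, function(g) min(match(g, ord)), numeric(1))
  groups <- groups[order(first_rank)]
  out <- character(k)
  for (g in seq_along(groups)) {
    for (i in groups[[g]]) out[i] <- paste0(out[i], letters[g])
  }
  out
}

#' Year-class trends in density and diversity, per production mode
#'
#' Joins a per-quadrat diversity profile to the site practice records,
#' groups quadrats (or field means) into consecutive-planting-year classes
#' and runs [anova_lsd()] per mode and response. Total seed density and
#' evenness are log(x+1)-transformed, the transform used to meet the
#' ANOVA's normality and homoscedasticity assumptions for those responses.
#'
#' @param profile output of [diversity_profile()].
#' @param practices practice records with `site_id` and
#'   `consecutive_years`.
#' @param responses profile columns to analyse.
#' @param unit `"quadrat"` (default) or `"field"` (field means as
#'   replicates).
#' @param alpha significance level.
#' @return data frame with one row per (mode, response, class): class
#'   statistics, letters, and the mode-level F, p, Shapiro and Levene
#'   p-values; the underlying `seedbank_trend` objects in attribute
#'   `"fits"`. Modes sampled in fewer than two year classes (or with a
#'   class of fewer than two replicates) cannot be tested; they are
#'   skipped and listed in attribute `"skipped_modes"`.
#' @export
trend_analysis <- function(profile, practices,
                           responses = c("total_density", "lambda",
                                         "evenness", "dominance"),
                           unit = c("quadrat", "field"), alpha = 0.05) {
  unit <- match.arg(unit)
  miss <- setdiff(unique(profile$site), practices$site_id)
  if (length(miss) > 0)
    stop("no practice record for site(s): ", paste(miss, collapse = ", "))
  years <- practices$consecutive_years[match(profile$site,
                                             practices$site_id)]
  profile$year_class <- year_class(years)
  if (unit == "field") {
    agg <- stats::aggregate(profile[responses],
                            by = profile[c("mode", "site", "field",
                                           "year_class")],
                            FUN = mean, na.rm = TRUE)
    profile <- agg
  }
  log_responses <- c("total_density", "evenness")
  fits <- list()
  rows <- list()
  skipped <- character()
  for (md in unique(profile$mode)) {
    sub <- profile[profile$mode == md, , drop = FALSE]
    cls <- droplevels(sub$year_class)
    if (nlevels(cls) < 2 || any(table(cls) < 2)) {
      # a mode sampled in fewer than two year classes cannot be tested
      skipped <- c(skipped, md)
      next
    }
    for (resp in responses) {
      tr <- if (resp %in% log_responses) "log1p" else "none"
      fit <- anova_lsd(sub[[resp]], sub$year_class, alpha = alpha,
                       transform = tr)
      fits[[paste(md, resp, sep = ":")]] <- fit
      tab <- fit$table
      rows[[length(rows) + 1]] <- data.frame(
        mode = md, response = resp, transform = tr, tab,
        F = fit$F, p_value = fit$p_value, shapiro_p = fit$shapiro_p,
        levene_p = fit$levene_p, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0)
    stop("no mode was sampled in at least 2 year classes")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "fits") <- fits
  attr(res, "skipped_modes") <- unique(skipped)
  res
}
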