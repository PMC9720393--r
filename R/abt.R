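#' Configuration for aggregated boosted trees
#'
#' Stagewise least-squares gradient boosting with depth-limited regression
#' trees: 500 trees, shrinkage 0.01, interaction depth 3, 50% bagging and a
#' minimum leaf size of 2, the standard aggregated-boosted-tree practice
#' for ecological driver attribution.
#'
#' @param n_trees number of boosting stages (>= 1).
#' @param shrinkage learning rate in (0, 1].
#' @param max_depth maximum tree depth.
#' @param bag_fraction subsample fraction per stage in (0, 1].
#' @param min_samples_leaf minimum observations per leaf.
#' @param seed integer seed for bagging.
#' @return an `abt_config` list.
#' @export
abt_config <- function(n_trees = 500, shrinkage = 0.01, max_depth = 3,
                       bag_fraction = 0.5, min_samples_leaf = 2,
                       seed = NULL) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (shrinkage <= 0 || shrinkage > 1) stop("shrinkage must be in (0, 1]")
  if (bag_fraction <= 0 || bag_fraction > 1)
    stop("bag_fraction must be in (0, 1]")
  if (max_depth < 1) stop("max_depth must be >= 1")
  structure(list(n_trees = as.integer(n_trees), shrinkage = shrinkage,
                 max_depth = as.integer(max_depth),
                 bag_fraction = bag_fraction,
                 min_samples_leaf = as.integer(min_samples_leaf),
                 seed = seed),
            class = "abt_config")
}

# Sum of squared-error split improvements per predictor for one fitted
# rpart tree: improvement of an internal node = its deviance minus the
# deviance of its two children (anova deviance = within-node SS).
tree_split_gains <- function(fit, vars) {
  gains <- stats::setNames(numeric(length(vars)), vars)
  frame <- fit$frame
  if (nrow(frame) < 3) return(gains)
  node <- as.integer(rownames(frame))
  internal <- which(frame$var != "<leaf>")
  for (i in internal) {
    kids <- match(c(2 * node[i], 2 * node[i] + 1), node)
    gain <- frame$dev[i] - sum(frame$dev[kids])
    v <- as.character(frame$var[i])
    gains[v] <- gains[v] + max(gain, 0)
  }
  gains
}

#' Fit a boosted regression tree model for one response
#'
#' Stagewise gradient boosting under squared-error loss: each stage fits a
#' depth-limited regression tree ([rpart::rpart]) to the current residuals
#' on a random `bag_fraction` subsample and adds `shrinkage` times its
#' prediction to the model. The relative influence of a predictor is the
#' sum over all splits on it of the squared-error improvement of the
#' split, normalized to sum to 100 over predictors. Categorical predictors
#' are split natively by the tree learner and their influence is attributed
#' to the variable as a whole.
#'
#' @param X data frame of predictors (numeric or factor/character).
#' @param y numeric response, one value per row of `X`.
#' @param cfg an [abt_config()].
#' @return list of class `abt_fit`: `influence` (named percentages summing
#'   to 100), `gains` (raw improvement sums), `loss_trace` (training MSE
#'   after each stage), `init` (intercept), `config`.
#' @export
fit_boosted_trees <- function(X, y, cfg = abt_config()) {
  X <- as.data.frame(X)
  n <- nrow(X)
  if (length(y) != n) stop("y must have one value per row of X")
  if (n < 4) stop("need at least 4 observations")
  if (stats::var(y) == 0)
    stop("constant response: influence undefined")
  if (n < 2 / cfg$bag_fraction)
    stop("too few observations for bag_fraction ", cfg$bag_fraction)
  X[] <- lapply(X, function(col) if (is.character(col)) factor(col) else col)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  vars <- names(X)
  ctrl <- rpart::rpart.control(
    maxdepth = cfg$max_depth, minbucket = cfg$min_samples_leaf,
    minsplit = 2 * cfg$min_samples_leaf, cp = 0, xval = 0,
    maxsurrogate = 0, usesurrogate = 0, maxcompete = 0
  )
  n_bag <- max(2L, as.integer(floor(cfg$bag_fraction * n)))
  fhat <- rep(mean(y), n)
  gains <- stats::setNames(numeric(length(vars)), vars)
  trace <- numeric(cfg$n_trees)
  dat <- X
  for (m in seq_len(cfg$n_trees)) {
    dat$.resid <- y - fhat
    bag <- sample.int(n, n_bag)
    fit <- rpart::rpart(.resid ~ ., data = dat[bag, , drop = FALSE],
                        method = "anova", control = ctrl)
    fhat <- fhat + cfg$shrinkage * stats::predict(fit, newdata = dat)
    trace[m] <- mean((y - fhat)^2)
    gains <- gains + tree_split_gains(fit, vars)
  }
  total <- sum(gains)
  if (total == 0) stop("no usable splits: predictors carry no signal")
  structure(list(influence = 100 * gains / total, gains = gains,
                 loss_trace = trace, init = mean(y), config = cfg),
            class = "abt_fit")
}

#' Relative influence of farming practices on guild composition
#'
#' Fits one boosted model per guild response (the per-field percentages of
#' total importance value held by grass, sedge and broadleaf weeds) on the
#' farming-practice predictors (rice variety plus the seven annual
#' quantities), then averages the per-response normalized influences with
#' equal weight and renormalizes to 100%.
#'
#' @param practices practice records with `site_id`, `rice_variety` and the
#'   [practice_covariates()] columns.
#' @param shares per-field guild shares from [guild_shares()] (columns
#'   `site`, `grass`, `sedge`, `broadleaf`); observations may equally be
#'   keyed per site.
#' @param cfg an [abt_config()].
#' @return list of class `abt_result`: `influence` (aggregated percentages
#'   summing to 100, decreasing), `per_response` (predictors x guilds
#'   matrix), `loss_trace` (stages x guilds), `n_obs`, `config`.
#' @export
abt_relative_influence <- function(practices, shares, cfg = abt_config()) {
  validate_practices(practices)
  key <- if ("site" %in% names(shares)) "site" else "site_id"
  miss <- setdiff(unique(shares[[key]]), practices$site_id)
  if (length(miss) > 0)
    stop("no practice record for site(s): ", paste(miss, collapse = ", "))
  if (!all(SEEDBANK_GUILDS %in% names(shares)))
    stop("shares must contain columns grass, sedge, broadleaf")
  pr_cols <- c("rice_variety", practice_covariates())
  X <- practices[match(shares[[key]], practices$site_id), pr_cols,
                 drop = FALSE]
  rownames(X) <- NULL
  per_resp <- matrix(NA_real_, nrow = length(pr_cols),
                     ncol = length(SEEDBANK_GUILDS),
                     dimnames = list(pr_cols, SEEDBANK_GUILDS))
  traces <- matrix(NA_real_, nrow = cfg$n_trees,
                   ncol = length(SEEDBANK_GUILDS),
                   dimnames = list(NULL, SEEDBANK_GUILDS))
  for (g in SEEDBANK_GUILDS) {
    sub_cfg <- cfg
    sub_cfg$seed <- if (is.null(cfg$seed)) NULL else
      child_seed(cfg$seed, match(g, SEEDBANK_GUILDS))
    fit <- fit_boosted_trees(X, shares[[g]], sub_cfg)
    per_resp[, g] <- fit$influence[pr_cols]
    traces[, g] <- fit$loss_trace
  }
  agg <- rowMeans(per_resp)
  agg <- 100 * agg / sum(agg)
  structure(list(influence = sort(agg, decreasing = TRUE),
                 per_response = per_resp, loss_trace = traces,
                 n_obs = nrow(X), config = cfg),
            class = "abt_result")
}
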