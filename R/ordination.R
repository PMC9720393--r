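#' Field-level community matrix of importance values
#'
#' Builds the fields x species matrix whose rows are the per-field
#' importance values (IV) from [phyto_table()]; species absent from a field
#' are 0, so every row sums to 3.
#'
#' @param survey a `seedbank_survey`.
#' @param practices optional practice records supplying `region` per site
#'   for row metadata.
#' @return numeric matrix with rownames `site:field`; row metadata (site,
#'   field, mode and, if available, region) in attribute `"meta"`.
#' @export
community_matrix <- function(survey, practices = NULL) {
  tab <- phyto_table(survey, by = c("site", "field"))
  rows <- unique(tab$stratum)
  if (length(rows) < 2) stop("need at least 2 fields for a community matrix")
  species <- sort(unique(tab$species))
  m <- matrix(0, nrow = length(rows), ncol = length(species),
              dimnames = list(rows, species))
  m[cbind(match(tab$stratum, rows), match(tab$species, species))] <- tab$IV
  meta <- unique(tab[c("stratum", "site", "field")])
  mode_of <- unique(survey[c("site", "mode")])
  meta$mode <- mode_of$mode[match(meta$site, mode_of$site)]
  if (!is.null(practices) && "region" %in% names(practices))
    meta$region <- practices$region[match(meta$site, practices$site_id)]
  meta <- meta[match(rows, meta$stratum), , drop = FALSE]
  rownames(meta) <- NULL
  attr(m, "meta") <- meta
  m
}

#' Bray-Curtis dissimilarity matrix
#'
#' d_ij = 1 - 2 sum_k min(x_ik, x_jk) / sum_k (x_ik + x_jk), equivalently
#' sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk); values in [0, 1].
#'
#' @param m non-negative abundance matrix (rows = communities).
#' @return symmetric dissimilarity matrix with zero diagonal, carrying the
#'   `"meta"` attribute of `m` if present.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative abundances")
  rs <- rowSums(m)
  pair_sum <- outer(rs, rs, "+")
  if (any(pair_sum[upper.tri(pair_sum)] == 0))
    stop("Bray-Curtis undefined for a pair of all-zero rows")
  manh <- as.matrix(stats::dist(m, method = "manhattan"))
  d <- manh / pair_sum
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  attr(d, "meta") <- attr(m, "meta")
  d
}

check_distance <- function(d) {
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || !isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix must have zero diagonal")
  if (any(dm < 0)) stop("distances must be non-negative")
  unname(dm)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Multi-start NMDS minimizing Kruskal's stress-1 by alternating monotone
#' regression (pool-adjacent-violators isotonic fit of configuration
#' distances against the dissimilarity order; ties handled by the primary
#' approach) with Guttman-transform majorization updates of the
#' configuration. The first start is the classical metric scaling solution
#' of the dissimilarities; remaining starts are seeded random Gaussian
#' configurations. The lowest-stress configuration is returned, centered
#' and rotated to its principal axes.
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @param k embedding dimension (default 2).
#' @param n_runs number of ordination starts (default 250).
#' @param max_iter,tol per-run iteration cap and stress-improvement
#'   stopping tolerance.
#' @param seed integer seed for the random starts.
#' @return list of class `seedbank_nmds`: `points` (n x k coordinates),
#'   `stress` (stress-1 of the best run), `n_runs`, `best_run`,
#'   `converged`.
#' @export
nmds <- function(d, k = 2, n_runs = 250, max_iter = 200, tol = 1e-7,
                 seed = NULL) {
  dm <- check_distance(d)
  n <- nrow(dm)
  if (n < k + 2) stop("need at least k + 2 points for a k-dimensional NMDS")
  if (!is.null(seed)) set.seed(seed)
  lt <- lower.tri(dm)
  delta <- dm[lt]
  scale0 <- stats::sd(delta) + mean(delta)
  init <- suppressWarnings(stats::cmdscale(dm, k = k))
  if (ncol(init) < k)
    init <- cbind(init, matrix(stats::rnorm(n * (k - ncol(init)),
                                            sd = 1e-4 * max(scale0, 1)),
                               n, k - ncol(init)))
  best <- NULL
  for (run in seq_len(n_runs)) {
    X0 <- if (run == 1) init else
      matrix(stats::rnorm(n * k, sd = scale0), n, k)
    fit <- nmds_single(X0, delta, lt, n, max_iter, tol)
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit
      best$run <- run
    }
  }
  X <- scale(best$X, center = TRUE, scale = FALSE)
  X <- X %*% svd(X)$v
  dimnames(X) <- list(rownames(as.matrix(d)), paste0("NMDS", seq_len(k)))
  structure(list(points = X, stress = best$stress, n_runs = n_runs,
                 best_run = best$run, converged = best$converged),
            class = "seedbank_nmds")
}

nmds_single <- function(X, delta, lt, n, max_iter, tol) {
  stress_prev <- Inf
  stress <- Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    D <- as.matrix(stats::dist(X))
    dvec <- D[lt]
    ssd <- sum(dvec^2)
    if (ssd == 0) { stress <- 0; converged <- TRUE; break }
    ord <- order(delta, dvec)  # primary approach to ties
    dhat <- numeric(length(dvec))
    dhat[ord] <- stats::isoreg(dvec[ord])$yf
    dhat <- pmax(dhat, 0)
    sh <- sum(dhat^2)
    if (sh > 0) dhat <- dhat * sqrt(ssd / sh)
    stress <- sqrt(sum((dhat - dvec)^2) / ssd)
    if (stress_prev - stress < tol) { converged <- TRUE; break }
    stress_prev <- stress
    # Guttman transform with disparities dhat
    W <- matrix(0, n, n)
    W[lt] <- ifelse(dvec > 0, dhat / dvec, 0)
    W <- W + t(W)
    X <- (rowSums(W) * X - W %*% X) / n
  }
  list(X = X, stress = stress, converged = converged)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance for a single grouping
#' factor, computed directly from squared inter-point distances:
#' SS_total = (1/n) sum_{i<j} d_ij^2,
#' SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2,
#' SS_between = SS_total - SS_within, and
#' pseudo-F = (SS_between / (g - 1)) / (SS_within / (n - g)). The p-value
#' is (b + 1) / (n_perm + 1) where b counts free row-label permutations
#' with a pseudo-F at least as large as observed, so the attainable minimum
#' is 1 / (n_perm + 1).
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param groups grouping factor (length n, at least 2 levels, not all
#'   singletons).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return list of class `seedbank_permanova`: `F`, `R2`, `p_value`,
#'   `n_perm`, `ss_total`, `ss_within`, `ss_between`, `df` (between,
#'   within).
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  dm <- check_distance(d)
  n <- nrow(dm)
  groups <- factor(groups)
  if (length(groups) != n) stop("groups must have one label per row")
  groups <- droplevels(groups)
  g <- nlevels(groups)
  if (g < 2) stop("need at least 2 groups")
  if (all(table(groups) == 1))
    stop("all groups are singletons: no within-group variation")
  if (!is.null(seed)) set.seed(seed)
  d2 <- dm^2
  ss_total <- sum(d2) / (2 * n)
  ss_within_for <- function(lab) {
    s <- 0
    for (lv in levels(lab)) {
      i <- which(lab == lv)
      if (length(i) > 1) s <- s + sum(d2[i, i]) / (2 * length(i))
    }
    s
  }
  f_for <- function(lab) {
    ssw <- ss_within_for(lab)
    ssb <- ss_total - ssw
    if (ssw <= 0) {
      if (ssb <= 0) return(0)
      return(Inf)
    }
    (ssb / (g - 1)) / (ssw / (n - g))
  }
  f_obs <- f_for(groups)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (f_for(sample(groups)) >= f_obs) exceed <- exceed + 1L
  }
  ss_within <- ss_within_for(groups)
  ss_between <- ss_total - ss_within
  structure(list(
    F = f_obs,
    R2 = if (ss_total > 0) ss_between / ss_total else 0,
    p_value = (exceed + 1) / (n_perm + 1),
    n_perm = n_perm,
    ss_total = ss_total,
    ss_within = ss_within,
    ss_between = ss_between,
    df = c(between = g - 1L, within = n - g)
  ), class = "seedbank_permanova")
}

#' Per-group confidence ellipses for ordination plots
#'
#' Normal-theory ellipses: per group the mean and covariance eigen-axes
#' scaled by sqrt of the chi-square quantile at `level` (2 df).
#'
#' @param coords n x 2 coordinate matrix.
#' @param groups grouping factor.
#' @param level confidence level (default 0.95).
#' @return data frame with one row per group: center, semi-axis lengths,
#'   orientation angle (radians) and a `degenerate` flag (TRUE when the
#'   group has fewer than 3 points or a rank-deficient covariance; such
#'   ellipses are omitted, i.e. parameters NA).
#' @export
confidence_ellipse <- function(coords, groups, level = 0.95) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("coords must have 2 columns")
  if (level < 0 || level >= 1) stop("level must be in [0, 1)")
  groups <- factor(groups)
  r <- sqrt(stats::qchisq(level, df = 2))
  out <- lapply(levels(groups), function(lv) {
    xy <- coords[groups == lv, , drop = FALSE]
    base <- data.frame(group = lv, cx = NA_real_, cy = NA_real_,
                       a = NA_real_, b = NA_real_, angle = NA_real_,
                       degenerate = TRUE, stringsAsFactors = FALSE)
    if (nrow(xy) < 3) return(base)
    S <- stats::cov(xy)
    ev <- eigen(S, symmetric = TRUE)
    if (ev$values[2] <= 1e-12 * max(ev$values[1], 1e-300)) return(base)
    data.frame(group = lv, cx = mean(xy[, 1]), cy = mean(xy[, 2]),
               a = r * sqrt(ev$values[1]), b = r * sqrt(ev$values[2]),
               angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
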