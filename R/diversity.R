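#' Quadrat-level diversity indices
#'
#' Species diversity of a single quadrat's seed counts. All logarithms are
#' natural.
#'
#' `shannon_index()`: H' = -sum p_i log p_i over species with n_i > 0.
#'
#' `simpson_index()`: lambda = 1 - sum p_i^2 (the Simpson diversity, i.e.
#' the complement of the concentration D = sum p_i^2).
#'
#' `evenness_index()`: the default `"alatalo"` variant is the modified Hill
#' ratio E = (1/D - 1) / (e^H' - 1), which equals 1 for perfectly even
#' communities of any richness. The `"complement"` variant reads the same
#' ratio with the Simpson complement lambda in place of the concentration
#' D, E = (1/lambda - 1) / (e^H' - 1); it is retained for auditability
#' because published index lists are sometimes typeset ambiguously between
#' the two, but it degenerates (E = 1/(S-1)^2) on even communities and is
#' not the default.
#'
#' `dominance_index()`: the finite-sample ecological dominance
#' C = sum n_i (n_i - 1) / (N (N - 1)), the probability that two seeds
#' drawn without replacement are conspecific; C tends to D as N grows.
#'
#' @param counts non-negative integer seed counts by species (zeros
#'   allowed and ignored).
#' @param variant evenness variant, `"alatalo"` (default) or
#'   `"complement"`.
#' @return the index value (a single number).
#' @name diversity_indices
NULL

check_counts <- function(counts) {
  if (any(counts < 0)) stop("negative seed count")
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("empty quadrat: diversity undefined")
  counts
}

#' @rdname diversity_indices
#' @export
shannon_index <- function(counts) {
  n <- check_counts(counts)
  p <- n / sum(n)
  -sum(p * log(p))
}

#' @rdname diversity_indices
#' @export
simpson_index <- function(counts) {
  n <- check_counts(counts)
  p <- n / sum(n)
  1 - sum(p^2)
}

#' @rdname diversity_indices
#' @export
evenness_index <- function(counts, variant = c("alatalo", "complement")) {
  variant <- match.arg(variant)
  n <- check_counts(counts)
  if (length(n) < 2)
    stop("evenness undefined for a single-species quadrat")
  p <- n / sum(n)
  D <- sum(p^2)
  H <- -sum(p * log(p))
  num <- if (variant == "alatalo") 1 / D - 1 else 1 / (1 - D) - 1
  num / (exp(H) - 1)
}

#' @rdname diversity_indices
#' @export
dominance_index <- function(counts) {
  n <- check_counts(counts)
  N <- sum(n)
  if (N < 2) stop("dominance undefined for fewer than 2 seeds")
  sum(n * (n - 1)) / (N * (N - 1))
}

#' Per-quadrat diversity profile of a survey
#'
#' Computes, for every quadrat, the total seed count N, species richness S,
#' Shannon H', Simpson lambda, evenness E, ecological dominance C and the
#' total seed density (via [counts_to_density()]).
#'
#' @param survey a `seedbank_survey` data frame.
#' @param evenness_variant passed to [evenness_index()].
#' @param strict if TRUE (default) degenerate quadrats (empty; single
#'   species for E; fewer than 2 seeds for C) raise an error naming the
#'   quadrat; if FALSE the affected index is NA.
#' @return data frame with one row per quadrat: `site`, `mode`, `field`,
#'   `quadrat`, `N`, `S`, `shannon`, `lambda`, `evenness`, `dominance`,
#'   `total_density`.
#' @export
diversity_profile <- function(survey, evenness_variant = "alatalo",
                              strict = TRUE) {
  parts <- survey_parts(survey)
  area <- survey_part_area(survey)
  key <- interaction(survey$site, survey$field, survey$quadrat, drop = TRUE)
  pieces <- split(seq_len(nrow(survey)), key)
  out <- lapply(pieces, function(i) {
    counts <- survey$count[i]
    id <- sprintf("site %s field %s quadrat %s", survey$site[i[1]],
                  survey$field[i[1]], survey$quadrat[i[1]])
    N <- sum(counts)
    S <- sum(counts > 0)
    safely <- function(f) {
      tryCatch(f(counts), error = function(e) {
        if (strict) stop(conditionMessage(e), " (", id, ")", call. = FALSE)
        NA_real_
      })
    }
    data.frame(
      site = survey$site[i[1]], mode = survey$mode[i[1]],
      field = survey$field[i[1]], quadrat = survey$quadrat[i[1]],
      N = N, S = S,
      shannon = safely(shannon_index),
      lambda = safely(simpson_index),
      evenness = safely(function(x) evenness_index(x, evenness_variant)),
      dominance = safely(dominance_index),
      total_density = counts_to_density(N, parts, area),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$site, res$field, res$quadrat), , drop = FALSE]
}
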