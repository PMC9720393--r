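# Naive brute-force re-implementations of the printed equations, kept
# deliberately loop-based and independent of the package's vectorized code
# paths, plus small random fixture generators.

naive_shannon <- function(counts) {
  n <- counts[counts > 0]
  N <- sum(n)
  h <- 0
  for (ni in n) h <- h - (ni / N) * log(ni / N)
  h
}

naive_simpson <- function(counts) {
  n <- counts[counts > 0]
  N <- sum(n)
  s <- 0
  for (ni in n) s <- s + (ni / N)^2
  1 - s
}

naive_evenness <- function(counts, variant = "alatalo") {
  n <- counts[counts > 0]
  N <- sum(n)
  D <- 0
  for (ni in n) D <- D + (ni / N)^2
  H <- naive_shannon(counts)
  num <- if (variant == "alatalo") 1 / D - 1 else 1 / (1 - D) - 1
  num / (exp(H) - 1)
}

naive_dominance <- function(counts) {
  n <- counts[counts > 0]
  N <- sum(n)
  s <- 0
  for (ni in n) s <- s + ni * (ni - 1)
  s / (N * (N - 1))
}

# counts: quadrats x species matrix for one stratum
naive_phyto <- function(counts, parts = 3, area = 0.016) {
  Q <- nrow(counts)
  keep <- colSums(counts) > 0
  counts <- counts[, keep, drop = FALSE]
  S <- ncol(counts)
  AF <- AD <- AA <- numeric(S)
  for (s in seq_len(S)) {
    occupied <- sum(counts[, s] > 0)
    AF[s] <- occupied / Q
    AD[s] <- sum(counts[, s]) / (Q * parts * area)
    AA[s] <- sum(counts[, s]) / occupied
  }
  RF <- AF / sum(AF)
  RD <- AD / sum(AD)
  RA <- AA / sum(AA)
  data.frame(species = colnames(counts), AF = AF, RF = RF, AD = AD,
             RD = RD, AA = AA, RA = RA, IV = RF + RD + RA,
             stringsAsFactors = FALSE)
}

naive_bray_curtis <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      mins <- 0
      tot <- 0
      for (k2 in seq_len(ncol(m))) {
        mins <- mins + min(m[i, k2], m[j, k2])
        tot <- tot + m[i, k2] + m[j, k2]
      }
      d[i, j] <- 1 - 2 * mins / tot
    }
  }
  d
}

naive_permanova_F <- function(dm, groups) {
  groups <- factor(groups)
  n <- nrow(dm)
  g <- nlevels(groups)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    ss_total <- ss_total + dm[i, j]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (lv in levels(groups)) {
    idx <- which(groups == lv)
    if (length(idx) < 2) next
    s <- 0
    for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx))
      s <- s + dm[idx[a], idx[b]]^2
    ss_within <- ss_within + s / length(idx)
  }
  ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
}

# random small quadrat-count matrix (quadrats x species), at least one seed
random_count_matrix <- function(max_q = 5, max_s = 4) {
  Q <- sample(2:max_q, 1)
  S <- sample(2:max_s, 1)
  m <- matrix(rpois(Q * S, lambda = sample(1:4, 1)), Q, S)
  if (sum(m) == 0) m[1, 1] <- 1L
  colnames(m) <- sprintf("sp%02d", seq_len(S))
  m
}

# wrap a count matrix as a one-mode survey data frame
matrix_to_survey <- function(m, mode = "RG", site = "S1", field = 1) {
  df <- expand.grid(quadrat = seq_len(nrow(m)), species = colnames(m),
                    stringsAsFactors = FALSE)
  df$count <- as.vector(m)
  df$site <- site
  df$mode <- mode
  df$field <- field
  as_survey(df[c("site", "mode", "field", "quadrat", "species", "count")])
}

tiny_design <- function(...) {
  survey_design(sites_per_mode = 1, quadrats_per_field = 3, ...)
}
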