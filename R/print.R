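#' @export
print.seedbank_permanova <- function(x, ...) {
  cat("One-way PERMANOVA (free permutation of rows)\n")
  cat(sprintf("  pseudo-F = %.4f on df (%d, %d)\n", x$F,
              x$df[["between"]], x$df[["within"]]))
  cat(sprintf("  R2 = %.4f   p = %.4g (%d permutations)\n",
              x$R2, x$p_value, x$n_perm))
  invisible(x)
}

#' @export
print.seedbank_nmds <- function(x, ...) {
  cat(sprintf("NMDS (%d points, k = %d)\n", nrow(x$points),
              ncol(x$points)))
  cat(sprintf("  stress-1 = %.4f  best run %d of %d  converged: %s\n",
              x$stress, x$best_run, x$n_runs, x$converged))
  invisible(x)
}

#' @export
print.abt_result <- function(x, ...) {
  cat(sprintf("Aggregated boosted trees (%d obs, %d trees per response)\n",
              x$n_obs, x$config$n_trees))
  cat("Relative influence (%):\n")
  print(round(x$influence, 2))
  invisible(x)
}

#' @export
print.seedbank_trend <- function(x, ...) {
  cat(sprintf("One-way ANOVA (%s transform): F = %.4f, p = %.4g\n",
              x$transform, x$F, x$p_value))
  cat(sprintf("  Shapiro-Wilk p = %.3g   Levene p = %.3g\n",
              x$shapiro_p, x$levene_p))
  print(x$table, row.names = FALSE)
  invisible(x)
}
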