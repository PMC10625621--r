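# Cohort-level statistical comparison of two mutation catalogs.

#' Two-sample t test on mutation-level quantities
#'
#' Thin wrapper around [stats::t.test()] defaulting to the Welch
#' (unequal-variance) flavor, with explicit handling of the degenerate
#' constant-data cases that `t.test()` refuses: when both groups have zero
#' variance the p-value is 1 if the means are equal and 0 in the limit
#' otherwise.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list of class `cohort_test` with `statistic`, `p_value`, `df`,
#'   `n_a`, `n_b`, `method`.
#' @export
welch_t_test <- function(x, y, var_equal = FALSE,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop_cohortnet("each group needs at least 2 observations",
                   "cohortnet_insufficient_data")
  res <- if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      list(statistic = 0, p_value = 1, df = NA_real_)
    } else {
      # zero-variance separation: statistic diverges, p -> 0
      list(statistic = sign(mean(x) - mean(y)) * Inf, p_value = 0,
           df = NA_real_)
    }
  } else {
    tt <- stats::t.test(x, y, var.equal = var_equal,
                        alternative = alternative)
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter))
  }
  structure(c(res, list(n_a = length(x), n_b = length(y),
                        method = if (var_equal) "student" else "welch",
                        alternative = alternative)),
            class = "cohort_test")
}

#' @export
print.cohort_test <- function(x, ...) {
  cat(sprintf("%s t-test (%s): t = %.4g, p = %.4g (n = %d vs %d)\n",
              if (x$method == "welch") "Welch" else "Student", x$alternative,
              x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Compare two mutation catalogs
#'
#' Partitions the union of both catalogs' unique mutations and mutated genes
#' into shared and cohort-specific sets, and tests whether the two groups of
#' mutations differ in per-patient frequency within a single reference
#' cohort (`frequency_source`, typically the larger somatic cohort) on the
#' `log10(N + 1)` scale. When pathogenicity scores are present in both
#' catalogs their distributions are compared too.
#'
#' By default the frequency comparison is restricted to mutations actually
#' observed in `frequency_source`; `include_absent = TRUE` instead scores
#' absent mutations as frequency 0.
#'
#' @param a,b `mutation_catalog` objects.
#' @param frequency_source catalog in which carrier counts of both groups
#'   are measured (defaults to `b`).
#' @param include_absent keep mutations absent from `frequency_source` with
#'   frequency 0 instead of dropping them.
#' @param alternative passed to [welch_t_test()].
#' @return object of class `cohort_comparison`.
#' @export
compare_catalogs <- function(a, b, frequency_source = b,
                             include_absent = FALSE,
                             alternative = "two.sided") {
  ua <- a$unique_mutations; ub <- b$unique_mutations
  shared <- intersect(ua, ub)
  comp <- list(
    cohort_a = a$cohort_name, cohort_b = b$cohort_name,
    shared_mutations = sort(shared),
    a_specific_mutations = sort(setdiff(ua, ub)),
    b_specific_mutations = sort(setdiff(ub, ua)),
    shared_genes = sort(intersect(a$mutated_genes, b$mutated_genes)),
    a_specific_genes = sort(setdiff(a$mutated_genes, b$mutated_genes)),
    b_specific_genes = sort(setdiff(b$mutated_genes, a$mutated_genes)))

  src <- frequency_source
  fa <- mutation_frequency(src, ua)
  fb <- mutation_frequency(src, ub)
  if (!include_absent) {
    fa <- fa[fa > 0]; fb <- fb[fb > 0]
  }
  if (length(fa) < 2 || length(fb) < 2)
    stop_cohortnet(
      "fewer than 2 mutations per group present in the frequency source",
      "cohortnet_insufficient_data")
  comp$frequency_test <- welch_t_test(fa, fb, alternative = alternative)

  pa <- a$records$pathogenicity[!is.na(a$records$pathogenicity)]
  pb <- b$records$pathogenicity[!is.na(b$records$pathogenicity)]
  comp$pathogenicity_test <-
    if (length(pa) >= 2 && length(pb) >= 2)
      welch_t_test(pa, pb, alternative = alternative) else NULL
  structure(comp, class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("Cohort comparison:", x$cohort_a, "vs", x$cohort_b, "\n")
  cat(sprintf("  mutations: %d shared, %d %s-specific, %d %s-specific\n",
              length(x$shared_mutations),
              length(x$a_specific_mutations), x$cohort_a,
              length(x$b_specific_mutations), x$cohort_b))
  cat(sprintf("  genes:     %d shared, %d %s-specific, %d %s-specific\n",
              length(x$shared_genes),
              length(x$a_specific_genes), x$cohort_a,
              length(x$b_specific_genes), x$cohort_b))
  cat("  frequency  "); print(x$frequency_test)
  if (!is.null(x$pathogenicity_test)) {
    cat("  pathogenicity "); print(x$pathogenicity_test)
  }
  invisible(x)
}

#' @export
summary.cohort_comparison <- function(object, ...) {
  data.frame(
    quantity = c("shared_mutations", "a_specific_mutations",
                 "b_specific_mutations", "shared_genes",
                 "frequency_t", "frequency_p"),
    value = c(length(object$shared_mutations),
              length(object$a_specific_mutations),
              length(object$b_specific_mutations),
              length(object$shared_genes),
              object$frequency_test$statistic,
              object$frequency_test$p_value))
}
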