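#' Chance-expected classification accuracy from group sizes
#'
#' If eggs were assigned to species at random in proportion to species
#' sample sizes, the probability of a correct assignment would be
#' `sum(n_i^2) / N^2`. This is the chance null against which observed
#' discriminant rates are compared; equal sizes across `k` groups give
#' exactly `1/k`, and for fixed total the null is minimised by equal
#' sizes.
#'
#' @param sizes Positive integer vector of per-group sample sizes.
#' @return One-row tibble with `expected_accuracy` (proportion) and
#'   `expected_correct` (`sum(n_i^2) / N`, a real count).
#' @export
expected_accuracy <- function(sizes) {
  sizes <- as.numeric(sizes)
  if (!length(sizes) || any(sizes < 1)) abort("sizes must be positive")
  N <- sum(sizes)
  tibble(expected_accuracy = sum(sizes^2) / N^2,
         expected_correct = sum(sizes^2) / N)
}

#' Wald binomial confidence-interval half-width, in percentage points
#'
#' `1.96 * sqrt(p (1 - p) / n) * 100` with `p = correct / n`.
#'
#' @param correct Number of successes (0 <= correct <= n).
#' @param n Number of trials (> 0).
#' @return Half-width in percentage points.
#' @export
binomial_wald_ci <- function(correct, n) {
  if (any(n <= 0)) abort("n must be positive")
  if (any(correct < 0 | correct > n)) abort("correct must lie in [0, n]")
  p <- correct / n
  1.96 * sqrt(p * (1 - p) / n) * 100
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' @param a,b First row of counts; @param c,d second row.
#' @param c,d See `a,b`.
#' @return Two-sided p-value. A table with an all-zero margin carries no
#'   information and returns `p = 1`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  if (any(m < 0) || any(m != round(m))) abort("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  fisher.test(m)$p.value
}

#' Welch's t-test on pooled midranks
#'
#' Both samples are replaced by their midranks in the pooled sample and
#' compared with the unequal-variances (Welch) t-test with
#' Welch-Satterthwaite degrees of freedom — a robust two-sample location
#' comparison for distributions of classification rates.
#'
#' @param values_a,values_b Numeric vectors (length >= 2 each).
#' @return One-row tibble with `statistic`, `df`, `p_value`. When both
#'   rank vectors are constant the statistic is 0 and `p = 1`.
#' @export
ranked_welch <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("both samples need at least 2 values")
  }
  r <- rank(c(values_a, values_b))
  ra <- r[seq_along(values_a)]
  rb <- r[-seq_along(values_a)]
  if (var(ra) == 0 && var(rb) == 0) {
    return(tibble(statistic = 0, df = NA_real_, p_value = 1))
  }
  tt <- t.test(ra, rb, var.equal = FALSE)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

# fisher table comparing correct/incorrect under chance vs observed;
# expected correct is rounded to the nearest whole egg
.expected_vs_observed_p <- function(expected_correct, observed_correct, n) {
  e <- round(expected_correct)
  fisher_exact_2x2(e, n - e, observed_correct, n - observed_correct)
}

#' Groupwise phenotypic-partitioning analysis
#'
#' For the parasitized (role `"host"`) or unparasitized species of a
#' phenotype table: the observed number of eggs classified to the correct
#' species (jack-knifed discriminant analysis, or multinomial logistic
#' resubstitution), the chance-expected number from relative sample
#' sizes, the accuracy with its Wald binomial CI, the improvement over
#' chance, and a Fisher's exact test of observed against expected
#' correct/incorrect counts.
#'
#' @param data Phenotype tibble with `species` and `role` columns.
#' @param group `"parasitized"` or `"unparasitized"`.
#' @param method `"dfa"` (jack-knifed) or `"logistic"` (resubstitution).
#' @param traits Trait columns.
#' @return One-row `group_analysis` tibble with columns `group`,
#'   `method`, `n`, `n_species`, `expected_correct`, `observed_correct`,
#'   `accuracy_pct`, `ci_halfwidth_pct`, `expected_accuracy_pct`,
#'   `improvement_pct`, `fisher_p`.
#' @export
groupwise_analysis <- function(data, group = c("parasitized", "unparasitized"),
                               method = c("dfa", "logistic"),
                               traits = egg_traits()) {
  group <- match.arg(group)
  method <- match.arg(method)
  sub <- filter(data, .data$role == group_roles(group))
  if (length(unique(sub$species)) < 2) {
    abort(paste0("need at least 2 species in the ", group, " group"))
  }
  sizes <- as.integer(table(sub$species))
  N <- nrow(sub)
  exp_res <- expected_accuracy(sizes)
  observed <- if (method == "dfa") {
    jackknife_accuracy(sub, group = "species", traits = traits)$correct
  } else {
    fit <- fit_multinomial_logistic(sub, group = "species", traits = traits)
    sum(predict(fit, sub) == sub$species)
  }
  acc <- 100 * observed / N
  expected_pct <- 100 * exp_res$expected_accuracy
  res <- tibble(
    group = group, method = method, n = N, n_species = length(sizes),
    expected_correct = exp_res$expected_correct,
    observed_correct = observed,
    accuracy_pct = acc,
    ci_halfwidth_pct = binomial_wald_ci(observed, N),
    expected_accuracy_pct = expected_pct,
    improvement_pct = acc - expected_pct,
    fisher_p = .expected_vs_observed_p(exp_res$expected_correct, observed, N)
  )
  class(res) <- c("group_analysis", class(res))
  res
}

#' Compare two groupwise analyses
#'
#' Fisher's exact tests across groups: do the groups differ in
#' chance-expected accuracy (a sample-size artefact check), and do they
#' differ in observed accuracy (the phenotypic contrast)?
#'
#' @param result_a,result_b `group_analysis` rows from
#'   [groupwise_analysis()].
#' @return Tibble with one row per comparison (`expected`, `observed`)
#'   and the Fisher p-value.
#' @export
compare_group_accuracy <- function(result_a, result_b) {
  p_exp <- fisher_exact_2x2(
    round(result_a$expected_correct), result_a$n - round(result_a$expected_correct),
    round(result_b$expected_correct), result_b$n - round(result_b$expected_correct)
  )
  p_obs <- fisher_exact_2x2(
    result_a$observed_correct, result_a$n - result_a$observed_correct,
    result_b$observed_correct, result_b$n - result_b$observed_correct
  )
  tibble(comparison = c("expected", "observed"),
         p_value = c(p_exp, p_obs))
}

#' Pairwise phenotypic-partitioning analysis
#'
#' For every unordered pair of species in a group: the two-group
#' jack-knifed classification accuracy and the pair's chance expectation
#' `(n_i^2 + n_j^2) / (n_i + n_j)^2`. The per-pair model is refitted on
#' just the two species of the (already cleaned) table.
#'
#' @inheritParams groupwise_analysis
#' @return Tibble with columns `species_a`, `species_b`, `n_a`, `n_b`,
#'   `expected_pct`, `observed_pct`.
#' @export
pairwise_analysis <- function(data, group = c("parasitized", "unparasitized"),
                              traits = egg_traits()) {
  group <- match.arg(group)
  sub <- filter(data, .data$role == group_roles(group))
  sp <- sort(unique(sub$species))
  if (length(sp) < 2) abort("need at least 2 species")
  pairs <- utils::combn(sp, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    two <- filter(sub, .data$species %in% pairs[, j])
    sizes <- as.integer(table(factor(two$species, levels = pairs[, j])))
    jk <- jackknife_accuracy(two, group = "species", traits = traits)
    tibble(species_a = pairs[1, j], species_b = pairs[2, j],
           n_a = sizes[1], n_b = sizes[2],
           expected_pct = 100 * expected_accuracy(sizes)$expected_accuracy,
           observed_pct = jk$accuracy_pct)
  })
}

#' Published groupwise classification counts (warbler and weaver study)
#'
#' Summary counts from the original museum-collection study of egg
#' phenotypes in southern Zambia: group sizes, chance-expected correct
#' counts and observed correct counts for parasitized and unparasitized
#' warblers (Cisticolidae, cuckoo finch system) and weavers (Ploceidae,
#' diederik cuckoo system), under jack-knifed discriminant analysis and
#' multinomial logistic regression. The raw per-egg data are a physical
#' museum collection with no public accession; these published summary
#' counts are the reference input for the summary-arithmetic checks.
#'
#' @return Tibble with columns `family`, `group`, `method`, `n`,
#'   `n_species`, `expected_correct`, `observed_correct`.
#' @export
study_summary_counts <- function() {
  tibble(
    family = rep(c("warbler", "warbler", "weaver", "weaver"), 2),
    group = rep(c("parasitized", "unparasitized"), 4),
    method = rep(c("dfa", "logistic"), each = 4),
    n = rep(c(205L, 219L, 339L, 46L), 2),
    n_species = rep(c(5L, 6L, 10L, 4L), 2),
    expected_correct = rep(c(44L, 42L, 46L, 12L), 2),
    observed_correct = c(169L, 120L, 216L, 46L, 189L, 145L, 269L, 46L)
  )
}

#' Summary arithmetic for published classification counts
#'
#' From group sizes and expected/observed correct counts, recomputes the
#' derived columns of the classic groupwise summary table: accuracy with
#' its Wald CI half-width, chance-expected accuracy, improvement over
#' chance, and the Fisher's exact p comparing expected and observed
#' counts.
#'
#' @param counts Tibble like [study_summary_counts()], with columns `n`,
#'   `expected_correct`, `observed_correct` (other columns carried
#'   through).
#' @return The input with columns `accuracy_pct`, `ci_halfwidth_pct`,
#'   `expected_accuracy_pct`, `improvement_pct`, `fisher_p` appended.
#' @export
summary_table_arithmetic <- function(counts = study_summary_counts()) {
  counts %>%
    mutate(
      accuracy_pct = 100 * .data$observed_correct / .data$n,
      ci_halfwidth_pct = binomial_wald_ci(.data$observed_correct, .data$n),
      expected_accuracy_pct = 100 * .data$expected_correct / .data$n,
      improvement_pct = .data$accuracy_pct - .data$expected_accuracy_pct,
      fisher_p = purrr::pmap_dbl(
        list(.data$expected_correct, .data$observed_correct, .data$n),
        function(e, o, n) .expected_vs_observed_p(e, o, n)
      )
    )
}
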