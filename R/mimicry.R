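#' Two-group jack-knifed accuracy between a host-race and a host
#'
#' Low accuracy means the race's eggs sit inside the host's phenotype
#' cloud (strong mimicry); high accuracy means they are distinguishable.
#'
#' @param race_eggs,host_eggs Phenotype tibbles (>= 3 eggs each).
#' @param traits Trait columns.
#' @return Accuracy percentage.
#' @export
hostrace_vs_host_accuracy <- function(race_eggs, host_eggs,
                                      traits = egg_traits()) {
  if (nrow(race_eggs) < 3 || nrow(host_eggs) < 3) {
    abort("both the race and the host need at least 3 eggs")
  }
  two <- bind_rows(
    mutate(race_eggs, .cmp = "race"),
    mutate(host_eggs, .cmp = "host")
  )
  jackknife_accuracy(two, group = ".cmp", traits = traits)$accuracy_pct
}

#' Host-race mimicry analysis
#'
#' For each parasitic host-race in the table, runs a two-group
#' jack-knifed discriminant analysis against its own host and against
#' every other host species in turn. The mimicry differential of a race
#' is its own-host accuracy minus the mean of its other-host accuracies:
#' negative values mean the race matches its own host better than other
#' hosts (specialist mimicry). Significance comes from a paired t-test
#' across races, pairing each race's own-host accuracy with its mean
#' other-host accuracy (so df = number of surviving races - 1). Races
#' with fewer than `min_race_n` eggs are reported but excluded from the
#' test.
#'
#' @param data Phenotype tibble containing `role = "parasite"` rows with
#'   `target_host` filled, plus the host rows.
#' @param min_race_n Minimum race sample size to enter the test.
#' @param traits Trait columns.
#' @return An `egg_mimicry` object: `$matrix` (tibble `race`, `host`,
#'   `comparison`, `accuracy_pct`), `$races` (per-race summary with
#'   `own_pct`, `mean_other_pct`, `difference_pct`, `n_eggs`,
#'   `included`), `$test` (tibble `mean_difference_pct`, `se_pct`,
#'   `statistic`, `df`, `p_value`).
#' @export
mimicry_analysis <- function(data, min_race_n = 3L, traits = egg_traits()) {
  races <- filter(data, .data$role == "parasite")
  hosts <- filter(data, .data$role == "host")
  if (!nrow(races)) abort("no parasite rows in the table")
  host_sp <- sort(unique(hosts$species))
  race_ids <- sort(unique(races$species))

  mat <- purrr::map_dfr(race_ids, function(rid) {
    re <- filter(races, .data$species == rid)
    own_host <- unique(re$target_host)
    if (length(own_host) != 1 || !own_host %in% host_sp) {
      abort(paste0("race '", rid, "' lacks a single valid target_host"))
    }
    if (nrow(re) < 3) {
      return(tibble(race = rid, host = own_host, comparison = "own",
                    accuracy_pct = NA_real_, n_eggs = nrow(re)))
    }
    purrr::map_dfr(host_sp, function(h) {
      he <- filter(hosts, .data$species == h)
      tibble(race = rid, host = h,
             comparison = if (h == own_host) "own" else "other",
             accuracy_pct = hostrace_vs_host_accuracy(re, he, traits),
             n_eggs = nrow(re))
    })
  })

  per_race <- mat %>%
    group_by(.data$race) %>%
    summarise(
      n_eggs = .data$n_eggs[1],
      own_pct = .data$accuracy_pct[.data$comparison == "own"][1],
      mean_other_pct = mean(.data$accuracy_pct[.data$comparison == "other"]),
      .groups = "drop"
    ) %>%
    mutate(difference_pct = .data$own_pct - .data$mean_other_pct,
           included = .data$n_eggs >= min_race_n & is.finite(.data$difference_pct))

  diffs <- per_race$difference_pct[per_race$included]
  test <- if (length(diffs) >= 2 && sd(diffs) > 0) {
    tt <- t.test(diffs)
    tibble(mean_difference_pct = mean(diffs),
           se_pct = sd(diffs) / sqrt(length(diffs)),
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value, n_races = length(diffs))
  } else if (length(diffs) >= 2) {
    tibble(mean_difference_pct = mean(diffs), se_pct = 0,
           statistic = 0, df = length(diffs) - 1, p_value = 1,
           n_races = length(diffs))
  } else {
    warn("fewer than 2 host-races survive the sample-size filter; test skipped")
    tibble(mean_difference_pct = if (length(diffs)) mean(diffs) else NA_real_,
           se_pct = NA_real_, statistic = NA_real_, df = NA_real_,
           p_value = NA_real_, n_races = length(diffs))
  }

  structure(list(matrix = mat, races = per_race, test = test,
                 min_race_n = min_race_n),
            class = "egg_mimicry")
}

#' @export
print.egg_mimicry <- function(x, ...) {
  cat("<egg_mimicry> ", nrow(x$races), " host-races (",
      sum(x$races$included), " in test)\n", sep = "")
  if (is.finite(x$test$p_value[1])) {
    cat(sprintf("mean own - other difference: %.1f%% (t = %.2f, df = %d, p = %.3g)\n",
                x$test$mean_difference_pct, x$test$statistic,
                as.integer(x$test$df), x$test$p_value))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.egg_mimicry <- function(x, ...) x$races

#' @exportS3Method generics::glance
glance.egg_mimicry <- function(x, ...) x$test
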