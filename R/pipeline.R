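#' Build a pipeline configuration
#'
#' Collects every dial of the end-to-end analysis in one list that
#' round-trips losslessly through JSON ([write_run_config()] /
#' [read_run_config()]). Every stochastic step derives its seed from the
#' single top-level `seed`.
#'
#' @param community Either a [community_spec()] (synthetic data) or a
#'   path to a phenotype CSV.
#' @param outlier_alpha Chi-square tail for outlier removal; `NULL`
#'   skips.
#' @param drop_collinear,transform Preprocessing switches (see
#'   [preprocess_phenotypes()]).
#' @param method Classifier for the groupwise analysis (`"dfa"` or
#'   `"logistic"`).
#' @param min_race_n Mimicry sample-size filter.
#' @param n_trees,run_physignal Candidate-tree count for the
#'   phylogenetic-signal stage, and whether to run it.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(community = warbler_community_spec(),
                       outlier_alpha = 0.001, drop_collinear = FALSE,
                       transform = FALSE, method = "dfa", min_race_n = 3L,
                       n_trees = 100L, run_physignal = TRUE, seed = 1L) {
  structure(
    list(community = community, outlier_alpha = outlier_alpha,
         drop_collinear = drop_collinear, transform = transform,
         method = match.arg(method, c("dfa", "logistic")),
         min_race_n = as.integer(min_race_n), n_trees = as.integer(n_trees),
         run_physignal = isTRUE(run_physignal), seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Sequences the whole study on one table: data generation (or loading),
#' data hygiene, groupwise and pairwise partitioning analyses for the
#' parasitized and unparasitized groups with their cross-group tests,
#' the host-race mimicry analysis, and per-trait phylogenetic signal
#' over a set of simulated candidate trees. Fully deterministic given
#' the config.
#'
#' @param config A [run_config()].
#' @return An `egg_pipeline` list: `data` (cleaned table), `traits`,
#'   `group_table` (one row per group, the groupwise summary),
#'   `group_comparison`, `pairwise` (long tibble over both groups),
#'   `pairwise_test` (ranked Welch contrast of observed pairwise
#'   accuracies), `mimicry`, `lambda_summary`, `provenance`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  raw <- stage("data", {
    if (inherits(config$community, "community_spec")) {
      generate_study(config$community)
    } else {
      read_phenotype_csv(config$community)
    }
  })
  prep <- stage("preprocess", preprocess_phenotypes(
    raw, outlier_alpha = config$outlier_alpha,
    drop_collinear = config$drop_collinear, transform = config$transform,
    seed = config$seed + 17L
  ))
  tbl <- prep$data
  traits <- prep$traits

  group_table <- stage("partition", bind_rows(
    groupwise_analysis(tbl, "parasitized", config$method, traits),
    groupwise_analysis(tbl, "unparasitized", config$method, traits)
  ))
  group_comparison <- compare_group_accuracy(group_table[1, ], group_table[2, ])

  pairwise <- stage("pairwise", bind_rows(
    mutate(pairwise_analysis(tbl, "parasitized", traits), group = "parasitized"),
    mutate(pairwise_analysis(tbl, "unparasitized", traits), group = "unparasitized")
  ))
  pairwise_test <- ranked_welch(
    pairwise$observed_pct[pairwise$group == "parasitized"],
    pairwise$observed_pct[pairwise$group == "unparasitized"]
  )

  mimicry <- if (any(tbl$role == "parasite")) {
    stage("mimicry", mimicry_analysis(tbl, config$min_race_n, traits))
  } else NULL

  lambda_summary <- if (config$run_physignal) {
    stage("physignal", {
      means <- species_trait_means(tbl, traits)
      trees <- simulate_trees(config$n_trees, nrow(means),
                              tip_labels = means$species,
                              seed = config$seed + 101L)
      summarize_over_trees(trees, means, traits)
    })
  } else NULL

  structure(
    list(data = tbl, traits = traits, group_table = group_table,
         group_comparison = group_comparison, pairwise = pairwise,
         pairwise_test = pairwise_test, mimicry = mimicry,
         lambda_summary = lambda_summary,
         provenance = list(seed = config$seed, method = config$method,
                           preprocessing = prep$sidecar,
                           package_version = as.character(utils::packageVersion("eggspace")))),
    class = "egg_pipeline"
  )
}

#' @export
print.egg_pipeline <- function(x, ...) {
  cat("<egg_pipeline> ", nrow(x$data), " eggs, ", length(x$traits),
      " traits\n", sep = "")
  print(as.data.frame(x$group_table[
    c("group", "method", "accuracy_pct", "expected_accuracy_pct",
      "improvement_pct", "fisher_p")]), digits = 3)
  invisible(x)
}

#' Write a pipeline report bundle
#'
#' Emits the machine-readable outputs of a run: the groupwise summary
#' table (TSV, one row per group), the pairwise long CSV, the mimicry
#' matrix CSV, the lambda summary TSV, and a JSON provenance log.
#'
#' @param result An `egg_pipeline` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_report <- function(result, dir) {
  stopifnot(inherits(result, "egg_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(result$group_table, file.path(dir, "group_table.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.csv(result$pairwise, file.path(dir, "pairwise.csv"), row.names = FALSE)
  if (!is.null(result$mimicry)) {
    write.csv(result$mimicry$matrix, file.path(dir, "mimicry_matrix.csv"),
              row.names = FALSE)
    write.table(result$mimicry$test, file.path(dir, "mimicry_test.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(result$lambda_summary)) {
    write.table(result$lambda_summary, file.path(dir, "lambda_summary.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(result$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# JSON round-trip for configs with a synthetic community
#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  payload <- config
  class(payload) <- NULL
  if (inherits(config$community, "community_spec")) {
    cs <- config$community
    payload$community <- list(
      type = "community_spec", seed = cs$seed,
      species = lapply(cs$species, function(s) {
        list(name = s$name, parasitized = s$parasitized,
             n_clutches = s$n_clutches, mean = unname(s$mean),
             cov = s$cov)
      }),
      host_races = lapply(cs$host_races, function(h) {
        list(target_host = h$target_host, fidelity = h$fidelity,
             n_eggs = h$n_eggs)
      })
    )
  } else {
    payload$community <- list(type = "csv", path = config$community)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  community <- if (identical(p$community$type, "community_spec")) {
    species <- lapply(p$community$species, function(s) {
      species_spec(s$name, s$parasitized, s$n_clutches, unlist(s$mean),
                   do.call(rbind, lapply(s$cov, unlist)))
    })
    races <- lapply(p$community$host_races, function(h) {
      host_race_spec(h$target_host, h$fidelity, h$n_eggs)
    })
    community_spec(species, races, seed = p$community$seed)
  } else {
    p$community$path
  }
  run_config(community = community, outlier_alpha = p$outlier_alpha,
             drop_collinear = p$drop_collinear, transform = p$transform,
             method = p$method, min_race_n = p$min_race_n,
             n_trees = p$n_trees, run_physignal = p$run_physignal,
             seed = p$seed)
}
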