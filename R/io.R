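#' Read / write phenotype tables as CSV
#'
#' The on-disk format is a plain CSV with the header
#' `species,clutch_id,role,target_host` followed by the ten trait
#' columns.
#'
#' @param data Phenotype tibble.
#' @param path File path.
#' @return `write_phenotype_csv()` returns `path` invisibly;
#'   `read_phenotype_csv()` returns a validated tibble.
#' @export
write_phenotype_csv <- function(data, path) {
  cols <- c("species", "clutch_id", "role", "target_host", egg_traits())
  keep <- intersect(cols, names(data))
  write.csv(data[keep], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_csv
#' @export
read_phenotype_csv <- function(path) {
  x <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  needed <- c("species", "clutch_id", "role")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    abort(paste0("phenotype CSV lacks column(s): ", paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(x$role), egg_roles())
  if (length(bad)) {
    abort(paste0("unknown role(s): ", paste(bad, collapse = ", ")))
  }
  if (!"target_host" %in% names(x)) x$target_host <- NA_character_
  x
}

#' Serialise a discriminant model to JSON
#'
#' @param model An `egg_lda`.
#' @param path JSON file path.
#' @return `write_lda_json()` returns `path` invisibly;
#'   `read_lda_json()` rebuilds the `egg_lda`.
#' @export
write_lda_json <- function(model, path) {
  stopifnot(inherits(model, "egg_lda"))
  payload <- list(
    levels = model$levels, counts = unname(model$counts),
    means = model$means, W = model$W, axes = model$axes,
    eigenvalues = model$eigenvalues, priors = unname(model$priors),
    grand_mean = unname(model$grand_mean), traits = model$traits,
    group = model$group, n = model$n
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lda_json
#' @export
read_lda_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  means <- matrix(unlist(p$means), length(p$levels), length(p$traits),
                  dimnames = list(p$levels, p$traits))
  if (is.matrix(p$means)) means <- p$means
  W <- p$W; axes <- p$axes
  dimnames(W) <- list(p$traits, p$traits)
  dimnames(means) <- list(p$levels, p$traits)
  dimnames(axes) <- list(p$traits, paste0("DF", seq_len(ncol(axes))))
  structure(
    list(levels = p$levels, counts = stats::setNames(p$counts, p$levels),
         means = means, W = W, Winv = solve(W), axes = axes,
         eigenvalues = p$eigenvalues,
         priors = stats::setNames(p$priors, p$levels),
         grand_mean = stats::setNames(p$grand_mean, p$traits),
         traits = p$traits, group = p$group, n = p$n),
    class = "egg_lda"
  )
}
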