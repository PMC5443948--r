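#' Specify one species of a synthetic egg community
#'
#' A species is a multivariate normal cloud in the 10-trait egg-phenotype
#' space (see [egg_traits()]): a mean vector and a within-species covariance.
#' Pattern traits are treated as proportions, so draws are clipped to
#' \[0, 1\] for those five traits.
#'
#' @param name Species label (unique within a community).
#' @param parasitized Logical; is this species a brood-parasite host?
#' @param n_clutches Number of clutches to simulate (>= 1).
#' @param mean Numeric 10-vector of trait means, in [egg_traits()] order.
#' @param cov 10 x 10 symmetric positive-semidefinite covariance matrix.
#' @return A `species_spec` list.
#' @export
species_spec <- function(name, parasitized, n_clutches, mean, cov) {
  stopifnot(is.character(name), length(name) == 1)
  n_clutches <- as.integer(n_clutches)
  if (is.na(n_clutches) || n_clutches < 1) abort("n_clutches must be >= 1")
  d <- length(egg_traits())
  if (length(mean) != d) abort("mean must have length 10 (one per trait)")
  if (!is.matrix(cov) || any(dim(cov) != d)) abort("cov must be 10 x 10")
  if (max(abs(cov - t(cov))) > 1e-8) {
    abort(paste0("covariance for species '", name, "' is not symmetric"))
  }
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    abort(paste0("covariance for species '", name,
                 "' is not positive semi-definite"))
  }
  structure(
    list(name = name, parasitized = isTRUE(parasitized),
         n_clutches = n_clutches,
         mean = stats::setNames(as.numeric(mean), egg_traits()),
         cov = cov),
    class = "species_spec"
  )
}

#' Specify a parasitic host-race
#'
#' A host-race lays eggs drawn from a mixture: with probability `fidelity`
#' from its target host's fitted trait distribution (specialist mimicry),
#' otherwise from the pooled distribution over all hosts (generalist
#' laying). `fidelity = 1` is a perfect specialist, `fidelity = 0` a pure
#' generalist.
#'
#' @param target_host Name of the host species this race specialises on.
#' @param fidelity Mimicry fidelity in \[0, 1\].
#' @param n_eggs Number of parasitic eggs to simulate (>= 0).
#' @return A `host_race_spec` list.
#' @export
host_race_spec <- function(target_host, fidelity, n_eggs) {
  stopifnot(is.character(target_host), length(target_host) == 1)
  if (!is.numeric(fidelity) || fidelity < 0 || fidelity > 1) {
    abort("fidelity must lie in [0, 1]")
  }
  n_eggs <- as.integer(n_eggs)
  if (is.na(n_eggs) || n_eggs < 0) abort("n_eggs must be >= 0")
  structure(list(target_host = target_host, fidelity = fidelity,
                 n_eggs = n_eggs),
            class = "host_race_spec")
}

#' Assemble a community specification
#'
#' @param species List of [species_spec()] objects with unique names.
#' @param host_races List of [host_race_spec()] objects; every
#'   `target_host` must name a parasitized species in `species`.
#' @param seed Integer seed controlling every draw made from this spec.
#' @return A `community_spec` list.
#' @export
community_spec <- function(species, host_races = list(), seed = 1L) {
  if (!length(species)) abort("at least one species is required")
  stopifnot(all(vapply(species, inherits, logical(1), "species_spec")))
  nms <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(nms)) abort("species names must be unique")
  par_names <- nms[vapply(species, `[[`, logical(1), "parasitized")]
  for (hr in host_races) {
    if (!inherits(hr, "host_race_spec")) abort("host_races must be host_race_spec objects")
    if (!hr$target_host %in% par_names) {
      abort(paste0("host-race target '", hr$target_host,
                   "' is not a parasitized species in the community"))
    }
  }
  structure(list(species = species, host_races = host_races,
                 seed = as.integer(seed)),
            class = "community_spec")
}

# default within-species covariance: equal trait SDs with induced
# correlations for the named trait pairs (the UV-MW / SW-LW collinearity
# the real photon catches show)
default_egg_cov <- function(trait_sd = 0.06,
                            collinear_pairs = list(c("uv", "mw"), c("sw", "lw")),
                            collinear_r = 0.9) {
  traits <- egg_traits()
  d <- length(traits)
  sds <- rep_len(trait_sd, d)
  R <- diag(d)
  for (pr in collinear_pairs) {
    i <- match(pr[1], traits); j <- match(pr[2], traits)
    if (is.na(i) || is.na(j)) abort("collinear pair names must be egg traits")
    R[i, j] <- R[j, i] <- collinear_r
  }
  S <- diag(sds) %*% R %*% diag(sds)
  dimnames(S) <- list(traits, traits)
  S
}

#' Draw a random community specification
#'
#' Species mean vectors sit at a common centre (0.5 on every trait) plus
#' independent normal offsets with standard deviation
#' `separation * trait_sd` per trait, so `separation` is the ratio of
#' between-species to within-species spread: 0 gives identical species,
#' values around 1 give heavily overlapping clouds, values of 3 or more
#' give well-partitioned species. Parasitized and unparasitized species
#' get their own separation dials so the two groups can differ in how
#' strongly they partition phenotypic space.
#'
#' @param n_parasitized,n_unparasitized Number of species per group.
#' @param clutches_parasitized,clutches_unparasitized Clutch counts,
#'   recycled across the species of each group.
#' @param separation_parasitized,separation_unparasitized Between-species
#'   spread per group, in units of the within-species trait SD.
#' @param trait_sd Within-species SD shared by all traits.
#' @param collinear_r Induced within-species correlation for the UV-MW and
#'   SW-LW photon-catch pairs.
#' @param race_fidelity If non-`NULL`, one host-race per parasitized
#'   species with this mimicry fidelity.
#' @param race_n Eggs per host-race, recycled.
#' @param seed Integer seed (controls the mean layout and all egg draws).
#' @return A `community_spec`.
#' @export
random_community_spec <- function(n_parasitized, n_unparasitized,
                                  clutches_parasitized = 40,
                                  clutches_unparasitized = 40,
                                  separation_parasitized = 1,
                                  separation_unparasitized = 1,
                                  trait_sd = 0.06,
                                  collinear_r = 0.9,
                                  race_fidelity = NULL,
                                  race_n = 20,
                                  seed = 1L) {
  d <- length(egg_traits())
  cov <- default_egg_cov(trait_sd = trait_sd, collinear_r = collinear_r)
  n_par <- as.integer(n_parasitized); n_unp <- as.integer(n_unparasitized)
  cl_par <- rep_len(clutches_parasitized, max(n_par, 1L))
  cl_unp <- rep_len(clutches_unparasitized, max(n_unp, 1L))
  species <- with_seed(as.integer(seed), {
    # species mean offsets share the within-species correlation structure,
    # so the collinear photon-catch pairs stay collinear in the pooled table
    mk <- function(prefix, k, sep, clutches, parasitized) {
      offsets <- if (k > 0) rmvn(k, rep(0, d), sep^2 * cov) else NULL
      lapply(seq_len(k), function(i) {
        mu <- 0.5 + offsets[i, ]
        species_spec(sprintf("%s%02d", prefix, i), parasitized,
                     clutches[i], mu, cov)
      })
    }
    c(if (n_par > 0) mk("host", n_par, separation_parasitized, cl_par, TRUE),
      if (n_unp > 0) mk("free", n_unp, separation_unparasitized, cl_unp, FALSE))
  })
  races <- list()
  if (!is.null(race_fidelity) && n_par > 0) {
    rn <- rep_len(race_n, n_par)
    races <- lapply(seq_len(n_par), function(i) {
      host_race_spec(sprintf("host%02d", i), race_fidelity, rn[i])
    })
  }
  community_spec(species, races, seed = seed)
}

#' Warbler-like community preset
#'
#' Emulates the structure of the Zambian warbler (Cisticolidae) dataset:
#' five parasitized species totalling 205 clutches, six unparasitized
#' species totalling 219 clutches, and five parasitic host-races of which
#' two have very small samples (n = 2 and n = 1, exercising the low-n
#' exclusion rule in [mimicry_analysis()]). Published per-species clutch
#' counts are not available, so totals are split across species by a fixed
#' arbitrary allocation (80/50/30/25/20 and 60/45/40/30/24/20). Parasitized
#' species are given stronger between-species separation than unparasitized
#' species, the contrast the warbler system shows.
#'
#' @param seed Integer seed.
#' @param separation_parasitized,separation_unparasitized Group separation
#'   dials (see [random_community_spec()]).
#' @param race_fidelity Host-race mimicry fidelity.
#' @return A `community_spec`.
#' @export
warbler_community_spec <- function(seed = 1L,
                                   separation_parasitized = 0.8,
                                   separation_unparasitized = 0.4,
                                   race_fidelity = 0.95) {
  spec <- random_community_spec(
    n_parasitized = 5, n_unparasitized = 6,
    clutches_parasitized = c(80, 50, 30, 25, 20),
    clutches_unparasitized = c(60, 45, 40, 30, 24, 20),
    separation_parasitized = separation_parasitized,
    separation_unparasitized = separation_unparasitized,
    seed = seed
  )
  race_n <- c(25, 20, 15, 2, 1)
  spec$host_races <- lapply(1:5, function(i) {
    host_race_spec(sprintf("host%02d", i), race_fidelity, race_n[i])
  })
  spec
}

clip_pattern_traits <- function(tbl) {
  mutate(tbl, across(all_of(pattern_traits()), ~ pmin(pmax(.x, 0), 1)))
}

rmvn <- function(n, mean, cov) {
  d <- length(mean)
  ev <- eigen(cov, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), d)
  z <- matrix(rnorm(n * d), n, d)
  sweep(z %*% t(L), 2, mean, `+`)
}

#' Generate a synthetic egg community
#'
#' Draws one row per egg from each species' multivariate normal trait
#' distribution. Each clutch receives a unique ID; with
#' `eggs_per_clutch > 1` a clutch shares a random clutch effect (70% of
#' the within-species covariance between clutches, 30% within).
#'
#' @param spec A [community_spec()].
#' @param eggs_per_clutch Eggs simulated per clutch (default 1, matching
#'   the one-egg-per-clutch analysis design).
#' @return A phenotype tibble with columns `species`, `clutch_id`, `egg`,
#'   `role`, `target_host` and the ten trait columns.
#' @export
generate_community <- function(spec, eggs_per_clutch = 1L) {
  stopifnot(inherits(spec, "community_spec"))
  eggs_per_clutch <- as.integer(eggs_per_clutch)
  stopifnot(eggs_per_clutch >= 1)
  traits <- egg_traits()
  out <- with_seed(spec$seed, {
    purrr::map_dfr(spec$species, function(sp) {
      nc <- sp$n_clutches
      if (eggs_per_clutch == 1L) {
        X <- rmvn(nc, sp$mean, sp$cov)
        eggn <- rep(1L, nc)
        cl <- seq_len(nc)
      } else {
        centres <- rmvn(nc, sp$mean, 0.7 * sp$cov)
        X <- do.call(rbind, lapply(seq_len(nc), function(i) {
          rmvn(eggs_per_clutch, centres[i, ], 0.3 * sp$cov)
        }))
        eggn <- rep(seq_len(eggs_per_clutch), times = nc)
        cl <- rep(seq_len(nc), each = eggs_per_clutch)
      }
      colnames(X) <- traits
      bind_cols(
        tibble(species = sp$name,
               clutch_id = sprintf("%s_c%03d", sp$name, cl),
               egg = eggn,
               role = if (sp$parasitized) "host" else "unparasitized",
               target_host = NA_character_),
        as_tibble(X)
      )
    })
  })
  clip_pattern_traits(out)
}

#' Add parasitic host-race eggs to a community table
#'
#' Each race egg is drawn, with probability `fidelity`, from a
#' multivariate normal fitted to its target host's eggs, and otherwise
#' from one fitted to the pooled eggs of all host species. Race rows are
#' flagged `role = "parasite"` with the target recorded in `target_host`.
#'
#' @param community Phenotype tibble from [generate_community()].
#' @param specs List of [host_race_spec()] objects.
#' @param seed Integer seed.
#' @return The race rows as a phenotype tibble (bind to the community with
#'   [dplyr::bind_rows()], or use [generate_study()]).
#' @export
generate_host_races <- function(community, specs, seed = 1L) {
  traits <- egg_traits()
  hosts <- filter(community, .data$role == "host")
  if (!nrow(hosts)) abort("community contains no host-role rows")
  pooled_mean <- colMeans(as.matrix(hosts[traits]))
  pooled_cov <- stats::cov(as.matrix(hosts[traits]))
  ridge <- function(S) S + diag(1e-10, ncol(S))
  out <- with_seed(as.integer(seed), {
    purrr::map_dfr(specs, function(hr) {
      own <- filter(hosts, .data$species == hr$target_host)
      if (nrow(own) < 2) {
        abort(paste0("target host '", hr$target_host,
                     "' missing or has fewer than 2 eggs"))
      }
      if (hr$n_eggs == 0) return(tibble())
      mu <- colMeans(as.matrix(own[traits]))
      S <- stats::cov(as.matrix(own[traits]))
      from_own <- rbinom(hr$n_eggs, 1, hr$fidelity) == 1
      X <- matrix(NA_real_, hr$n_eggs, length(traits),
                  dimnames = list(NULL, traits))
      if (any(from_own)) X[from_own, ] <- rmvn(sum(from_own), mu, ridge(S))
      if (any(!from_own)) {
        X[!from_own, ] <- rmvn(sum(!from_own), pooled_mean, ridge(pooled_cov))
      }
      race <- paste0("race_", hr$target_host)
      bind_cols(
        tibble(species = race,
               clutch_id = sprintf("%s_c%03d", race, seq_len(hr$n_eggs)),
               egg = 1L, role = "parasite", target_host = hr$target_host),
        as_tibble(X)
      )
    })
  })
  if (nrow(out)) clip_pattern_traits(out) else out
}

#' Generate a full synthetic study: community plus host-races
#'
#' @param spec A [community_spec()]; its `host_races` (if any) are drawn
#'   with a seed offset from the community seed.
#' @param eggs_per_clutch Passed to [generate_community()].
#' @return Phenotype tibble of host, unparasitized and parasite rows.
#' @export
generate_study <- function(spec, eggs_per_clutch = 1L) {
  comm <- generate_community(spec, eggs_per_clutch)
  if (length(spec$host_races)) {
    races <- generate_host_races(comm, spec$host_races,
                                 seed = spec$seed + 1L)
    comm <- bind_rows(comm, races)
  }
  comm
}
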