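#' Pairwise great-circle distance matrix between zoos
#'
#' @param zoos zoo data.frame (zoo_id, latitude, longitude).
#' @return symmetric matrix of distances in km, zero diagonal, dimnames =
#'   zoo ids.
#' @export
pairwise_distance_matrix <- function(zoos) {
  stopifnot(nrow(zoos) >= 1)
  n <- nrow(zoos)
  lat <- zoos$latitude; lon <- zoos$longitude
  d <- matrix(0, n, n, dimnames = list(zoos$zoo_id, zoos$zoo_id))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      dij <- haversine_km(lat[i], lon[i], lat[j], lon[j])
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  d
}

# species x zoo count matrix aligned to the distance-matrix zoo order
holdings_matrix <- function(dataset, species_ids = NULL, zoo_ids = NULL) {
  if (is.null(zoo_ids)) zoo_ids <- dataset$zoos$zoo_id
  if (is.null(species_ids)) species_ids <- sort(unique(dataset$holdings$species_id))
  h <- dataset$holdings
  C <- matrix(0, length(species_ids), length(zoo_ids),
              dimnames = list(species_ids, zoo_ids))
  keep <- h$species_id %in% species_ids
  h <- h[keep, , drop = FALSE]
  C[cbind(match(h$species_id, species_ids), match(h$zoo_id, zoo_ids))] <- h$count
  C
}

#' Global zoo population totals per species
#'
#' @param dataset a `zoo_dataset`.
#' @return named integer vector: total individuals across all zoos, for every
#'   species with at least one holding.
#' @export
species_global_totals <- function(dataset) {
  stopifnot(inherits(dataset, "zoo_dataset"))
  t <- tapply(dataset$holdings$count, dataset$holdings$species_id, sum)
  out <- as.integer(t)
  names(out) <- names(t)
  out[order(names(out))]
}

#' Metapopulation size of a species within a zoo cluster
#'
#' Sums the species' holdings over the member zoos of a cluster; zoos not
#' holding the species contribute zero.
#'
#' @param species_id species identifier.
#' @param member_zoos character vector of zoo ids in the cluster.
#' @param holdings holdings data.frame.
#' @return integer number of individuals.
#' @export
metapopulation_size <- function(species_id, member_zoos, holdings) {
  idx <- holdings$species_id == species_id & holdings$zoo_id %in% member_zoos
  sum(holdings$count[idx])
}

#' Threatened species eligible for the cluster analysis
#'
#' Threatened species of a class whose network-wide total is at least `m`
#' individuals; species that can never reach the threshold even when pooling
#' every zoo are excluded.
#'
#' @param dataset a `zoo_dataset`.
#' @param class_name taxonomic class.
#' @param m metapopulation threshold (individuals).
#' @param strict if TRUE require total > m (strictly more); default FALSE
#'   (at least m).
#' @return character vector of species ids, sorted.
#' @export
eligible_species <- function(dataset, class_name, m, strict = FALSE) {
  stopifnot(inherits(dataset, "zoo_dataset"))
  sp <- dataset$species
  cand <- sp$species_id[sp$class_name == class_name & is_threatened(sp$category)]
  totals <- species_global_totals(dataset)
  totals <- totals[names(totals) %in% cand]
  ok <- if (strict) totals > m else totals >= m
  sort(names(totals)[ok])
}

# core engine: for focal-zoo indices `focal` and one radius, compute for each
# species (rows of C) the attained-threshold indicator mean and the cluster
# size means. A = membership matrix rows restricted to focal zoos.
cluster_stats_for_focals <- function(C, dmat, r, m, focal, strict = FALSE) {
  A <- dmat[focal, , drop = FALSE] <= r
  storage.mode(A) <- "double"
  nzoos <- rowSums(A)                       # cluster size per focal
  N <- C %*% t(A)                           # species x focal individuals
  H <- (C > 0) %*% t(A)                     # species x focal zoos-with-species
  hit <- if (strict) N > m else N >= m
  list(p = rowMeans(hit),
       mean_zoos = mean(nzoos),
       mean_zoos_with_species = rowMeans(H))
}

#' Exhaustive cluster-attainment probability
#'
#' Deterministic oracle for the Monte Carlo procedure: every zoo in turn is
#' taken as the focal zoo of a radius-`r` cluster (membership is inclusive,
#' distance <= r, so the focal zoo is always a member), and the proportion of
#' focal zoos whose cluster pools at least `m` individuals of the species is
#' returned, together with the exact average cluster size and average number
#' of member zoos holding the species.
#'
#' @param species_id species identifier.
#' @param r cluster radius in km.
#' @param m metapopulation threshold.
#' @param dmat distance matrix from [pairwise_distance_matrix()].
#' @param holdings holdings data.frame.
#' @param strict use N > m instead of N >= m.
#' @return list with `p`, `mean_zoos`, `mean_zoos_with_species`.
#' @export
exhaustive_cluster_probability <- function(species_id, r, m, dmat, holdings,
                                           strict = FALSE) {
  C <- holdings_matrix(list(holdings = holdings), species_ids = species_id,
                       zoo_ids = rownames(dmat))
  s <- cluster_stats_for_focals(C, dmat, r, m, seq_len(nrow(dmat)), strict)
  list(p = unname(s$p), mean_zoos = s$mean_zoos,
       mean_zoos_with_species = unname(s$mean_zoos_with_species))
}

#' Monte Carlo cluster-attainment probability
#'
#' The resampling procedure itself: at each of `iterations` steps a focal zoo
#' is drawn uniformly at random *with replacement* from all zoos, its
#' radius-`r` cluster is formed, and the indicator records whether the
#' cluster pools at least `m` individuals of the species. Returns the
#' indicator mean and the mean cluster sizes over the sampled clusters.
#'
#' @inheritParams exhaustive_cluster_probability
#' @param iterations number of focal-zoo draws (default 2,000).
#' @param seed optional integer seed.
#' @return list with `p`, `mean_zoos`, `mean_zoos_with_species`.
#' @export
mc_cluster_probability <- function(species_id, r, m, dmat, holdings,
                                   iterations = 2000, seed = NULL,
                                   strict = FALSE) {
  stopifnot(iterations >= 1, r >= 0)
  if (!is.null(seed)) set.seed(seed)
  focal <- sample.int(nrow(dmat), iterations, replace = TRUE)
  C <- holdings_matrix(list(holdings = holdings), species_ids = species_id,
                       zoo_ids = rownames(dmat))
  s <- cluster_stats_for_focals(C, dmat, r, m, focal, strict)
  list(p = unname(s$p), mean_zoos = s$mean_zoos,
       mean_zoos_with_species = unname(s$mean_zoos_with_species))
}

#' Default radius grid
#'
#' 100 km increments from 100 km up to `rmax` (default 10,000 km).
#' @param rmax maximum radius in km.
#' @param step increment in km.
#' @return numeric vector of radii.
#' @export
radius_grid <- function(rmax = 10000, step = 100) {
  seq(step, rmax, by = step)
}

# joint curve computation for several species of one class/threshold.
# Returns list of cluster_curve objects keyed by species id.
compute_curves <- function(dataset, species_ids, m, grid,
                           engine = c("exhaustive", "monte_carlo"),
                           iterations = 2000, seed = NULL, dmat = NULL,
                           strict = FALSE) {
  engine <- match.arg(engine)
  if (is.null(dmat)) dmat <- pairwise_distance_matrix(dataset$zoos)
  stopifnot(all(diff(grid) > 0))
  if (!is.null(seed)) set.seed(seed)
  C <- holdings_matrix(dataset, species_ids = species_ids,
                       zoo_ids = rownames(dmat))
  n_r <- length(grid)
  P <- matrix(NA_real_, length(species_ids), n_r,
              dimnames = list(species_ids, NULL))
  ZW <- P
  MZ <- numeric(n_r)
  for (k in seq_len(n_r)) {
    focal <- if (engine == "exhaustive") seq_len(nrow(dmat))
             else sample.int(nrow(dmat), iterations, replace = TRUE)
    s <- cluster_stats_for_focals(C, dmat, grid[k], m, focal, strict)
    P[, k] <- s$p
    ZW[, k] <- s$mean_zoos_with_species
    MZ[k] <- s$mean_zoos
  }
  lapply(stats::setNames(species_ids, species_ids), function(id) {
    structure(list(species_id = id, m = m, engine = engine,
                   iterations = if (engine == "monte_carlo") iterations else NA_integer_,
                   seed = seed,
                   curve = data.frame(radius_km = grid,
                                      p = unname(P[id, ]),
                                      mean_zoos = MZ,
                                      mean_zoos_with_species = unname(ZW[id, ]))),
              class = "cluster_curve")
  })
}

#' Cluster-attainment curve for one species
#'
#' Evaluates the attainment probability and mean zoo counts over a radius
#' grid. Errors if the species' network-wide total never reaches `m`
#' (use [eligible_species()] to find the analysable species).
#'
#' @param dataset a `zoo_dataset`.
#' @param species_id species identifier.
#' @param m metapopulation threshold.
#' @param grid strictly increasing radius grid in km (default
#'   [radius_grid()]: 100, 200, ..., 10,000).
#' @param engine `"exhaustive"` (every zoo as focal; exact) or
#'   `"monte_carlo"` (random focal zoos, the published procedure).
#' @param iterations Monte Carlo iterations per radius (default 2,000).
#' @param seed optional integer seed.
#' @param dmat optional precomputed distance matrix.
#' @param strict use N > m instead of N >= m.
#' @return a `cluster_curve`: list with a `curve` data.frame (radius_km, p,
#'   mean_zoos, mean_zoos_with_species) and metadata.
#' @export
species_cluster_curve <- function(dataset, species_id, m, grid = radius_grid(),
                                  engine = c("exhaustive", "monte_carlo"),
                                  iterations = 2000, seed = NULL, dmat = NULL,
                                  strict = FALSE) {
  stopifnot(inherits(dataset, "zoo_dataset"))
  totals <- species_global_totals(dataset)
  tot <- if (species_id %in% names(totals)) totals[[species_id]] else 0L
  reach <- if (strict) tot > m else tot >= m
  if (!reach) {
    stop(sprintf(paste0("species '%s' never reaches threshold %d ",
                        "(network total %d); see eligible_species()"),
                 species_id, m, tot), call. = FALSE)
  }
  compute_curves(dataset, species_id, m, grid, engine = match.arg(engine),
                 iterations = iterations, seed = seed, dmat = dmat,
                 strict = strict)[[1]]
}

#' @export
print.cluster_curve <- function(x, ...) {
  cat(sprintf("<cluster_curve> species %s, m=%d, engine %s, %d radii (p: %.3f..%.3f)\n",
              x$species_id, x$m, x$engine, nrow(x$curve),
              min(x$curve$p), max(x$curve$p)))
  invisible(x)
}

#' Class-level probability-to-distance ratio curve
#'
#' Averages, over the eligible species of a class, the ratio of the
#' attainment probability to the radial distance:
#' R(r) = (1/I) * sum_i p_i(r) / r. Large R means a high chance of
#' assembling the threshold metapopulation within a comparatively small
#' radius.
#'
#' @param curves list of `cluster_curve`s for the eligible species (all on
#'   the same grid and threshold), e.g. from [class_cluster_curves()].
#' @param class_name label for the class the curves belong to.
#' @return a `ratio_curve`: data.frame (radius_km, ratio) plus metadata
#'   `class_name`, `m`, `n_species`.
#' @export
class_ratio_curve <- function(curves, class_name = NA_character_) {
  if (!length(curves)) {
    stop(sprintf("no eligible species for class '%s': cannot form ratio curve",
                 class_name), call. = FALSE)
  }
  stopifnot(all(vapply(curves, inherits, logical(1), "cluster_curve")))
  grid <- curves[[1]]$curve$radius_km
  m <- curves[[1]]$m
  for (cv in curves) {
    stopifnot(identical(cv$curve$radius_km, grid), cv$m == m)
  }
  if (any(grid <= 0)) stop("ratio curve requires strictly positive radii", call. = FALSE)
  P <- vapply(curves, function(cv) cv$curve$p, numeric(length(grid)))
  ratio <- rowMeans(P) / grid
  structure(list(class_name = class_name, m = m, n_species = length(curves),
                 curve = data.frame(radius_km = grid, ratio = ratio)),
            class = "ratio_curve")
}

#' Curves for all eligible species of a class
#'
#' @inheritParams species_cluster_curve
#' @param class_name taxonomic class.
#' @return named list of `cluster_curve`s (may be empty).
#' @export
class_cluster_curves <- function(dataset, class_name, m, grid = radius_grid(),
                                 engine = c("exhaustive", "monte_carlo"),
                                 iterations = 2000, seed = NULL, dmat = NULL,
                                 strict = FALSE) {
  ids <- eligible_species(dataset, class_name, m, strict = strict)
  if (!length(ids)) return(list())
  compute_curves(dataset, ids, m, grid, engine = match.arg(engine),
                 iterations = iterations, seed = seed, dmat = dmat,
                 strict = strict)
}

#' Optimal cluster for a class and threshold
#'
#' Finds the grid radius maximizing the probability-to-distance ratio
#' (smallest radius on ties) and reports the species-averaged summary
#' statistics there: mean attainment probability, mean number of zoos in
#' the cluster, and mean number of member zoos holding the species.
#'
#' @param ratio_curve a `ratio_curve`.
#' @param curves the per-species `cluster_curve`s the ratio was built from.
#' @return an `optimal_cluster`: one-row data.frame with class, threshold,
#'   species_in_cluster, radial_distance_km, probability,
#'   avg_zoos_in_cluster, avg_zoos_with_species.
#' @export
optimal_cluster <- function(ratio_curve, curves) {
  stopifnot(inherits(ratio_curve, "ratio_curve"), length(curves) >= 1)
  k <- which.max(ratio_curve$curve$ratio)   # which.max returns first maximum
  r_star <- ratio_curve$curve$radius_km[k]
  p <- mean(vapply(curves, function(cv) cv$curve$p[k], numeric(1)))
  mz <- mean(vapply(curves, function(cv) cv$curve$mean_zoos[k], numeric(1)))
  zw <- mean(vapply(curves, function(cv) cv$curve$mean_zoos_with_species[k],
                    numeric(1)))
  out <- data.frame(class = ratio_curve$class_name,
                    threshold = ratio_curve$m,
                    species_in_cluster = ratio_curve$n_species,
                    radial_distance_km = r_star,
                    probability = p,
                    avg_zoos_in_cluster = mz,
                    avg_zoos_with_species = zw,
                    stringsAsFactors = FALSE)
  class(out) <- c("optimal_cluster", class(out))
  out
}

#' Optimal-cluster table over classes and thresholds
#'
#' The end-to-end spatial analysis: for every taxonomic class present in the
#' dataset and every threshold, computes per-species attainment curves, the
#' class ratio curve, and its optimum. Classes with no eligible species for
#' a given threshold are skipped with a message.
#'
#' @param dataset a `zoo_dataset`.
#' @param thresholds metapopulation thresholds (default 50, 100, 250).
#' @param grid radius grid in km.
#' @param engine,iterations,seed,strict passed to the curve computation.
#' @return data.frame, one row per (class, threshold) with eligible species.
#' @export
cluster_report <- function(dataset, thresholds = c(50, 100, 250),
                           grid = radius_grid(),
                           engine = c("exhaustive", "monte_carlo"),
                           iterations = 2000, seed = NULL, strict = FALSE) {
  stopifnot(inherits(dataset, "zoo_dataset"))
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  dmat <- pairwise_distance_matrix(dataset$zoos)
  classes <- sort(unique(dataset$species$class_name))
  rows <- list()
  for (cl in classes) {
    for (m in thresholds) {
      curves <- class_cluster_curves(dataset, cl, m, grid = grid,
                                     engine = engine, iterations = iterations,
                                     dmat = dmat, strict = strict)
      if (!length(curves)) {
        message(sprintf("class %s: no eligible species at threshold %d; skipped",
                        cl, m))
        next
      }
      rc <- class_ratio_curve(curves, class_name = cl)
      rows[[length(rows) + 1L]] <- optimal_cluster(rc, curves)
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flatten cluster curves into a long data.frame
#'
#' @param curves named list of `cluster_curve`s.
#' @return data.frame with species, radius_km, p, mean_zoos,
#'   mean_zoos_with_species.
#' @export
curves_to_df <- function(curves) {
  if (!length(curves)) {
    return(data.frame(species = character(0), radius_km = numeric(0),
                      p = numeric(0), mean_zoos = numeric(0),
                      mean_zoos_with_species = numeric(0)))
  }
  out <- do.call(rbind, lapply(curves, function(cv) {
    cbind(data.frame(species = cv$species_id, stringsAsFactors = FALSE),
          cv$curve)
  }))
  rownames(out) <- NULL
  out
}
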