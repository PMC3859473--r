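#' Define a synthetic zoo-network scenario
#'
#' A scenario states the world the generator draws from: how many zoos and
#' where (spatially clustered continental regions), the per-order world
#' checklist, how zoos collect species (holding probability or a fixed
#' number of held species per order, and a selection bias `beta` towards
#' threatened species), and the heavy-tailed law of per-species global
#' abundances. `beta = 1` is the null of unplanned collection; `beta > 1`
#' over-collects threatened species of that order, `beta = 0` avoids them.
#'
#' The defaults describe a small demonstration network: 20 zoos split across
#' two regions roughly 7,600 km apart (western Europe and central North
#' America), six orders spanning four terrestrial-vertebrate classes with
#' species totals spanning two orders of magnitude, and a Pareto abundance
#' law under which most species have fewer than 100 individuals and a small
#' fraction exceed 1,000.
#'
#' @param n_zoos number of zoos.
#' @param regions data.frame with columns lat, lon (region centre, degrees),
#'   share (fraction of zoos; must sum to 1) and spread_km (s.d. of the
#'   scatter around the centre).
#' @param orders data.frame with columns class_name, order_name, n_total,
#'   n_threatened, and optionally beta (default 1) and z_target (fixed
#'   number of held species; NA = draw from Binomial(n_total, holding_prob)).
#' @param holding_prob probability a world species is held somewhere in the
#'   network, when z_target is NA.
#' @param abundance list(shape, scale, cap): species totals are
#'   `round(scale * U^(-1/shape))` truncated at `cap` — a discretized Pareto.
#' @param zoo_intensity mean number of holding zoos per species scales as
#'   `zoo_intensity * log10(1 + total)`.
#' @param range_clustering if TRUE, a species' holding zoos are drawn near a
#'   species-specific anchor zoo (distance-decay with `range_sigma_km`)
#'   instead of uniformly.
#' @param range_sigma_km s.d. of the distance-decay kernel, km.
#' @param seed default seed used by [generate_dataset()].
#' @return an object of class `zoo_scenario`.
#' @export
synthetic_scenario <- function(n_zoos = 20,
                               regions = data.frame(
                                 lat = c(48, 40), lon = c(10, -95),
                                 share = c(0.6, 0.4),
                                 spread_km = c(500, 600)),
                               orders = data.frame(
                                 class_name = c("Mammalia", "Mammalia", "Aves",
                                                "Aves", "Reptilia", "Amphibia"),
                                 order_name = c("Primates", "Rodentia",
                                                "Passeriformes", "Psittaciformes",
                                                "Testudines", "Caudata"),
                                 n_total = c(400, 2200, 5000, 350, 300, 600),
                                 n_threatened = c(120, 400, 600, 100, 150, 250),
                                 stringsAsFactors = FALSE),
                               holding_prob = 0.15,
                               abundance = list(shape = 1.2, scale = 35,
                                                cap = 20000),
                               zoo_intensity = 3,
                               range_clustering = FALSE,
                               range_sigma_km = 1500,
                               seed = 1L) {
  stopifnot(n_zoos >= 1,
            abs(sum(regions$share) - 1) < 1e-8,
            all(regions$spread_km >= 0),
            all(c("class_name", "order_name", "n_total", "n_threatened")
                %in% names(orders)),
            all(orders$n_threatened <= orders$n_total),
            all(orders$n_total > 0),
            holding_prob > 0, holding_prob <= 1,
            abundance$shape > 0, abundance$scale >= 1, abundance$cap >= 1,
            zoo_intensity > 0)
  if (is.null(orders$beta)) orders$beta <- 1
  if (is.null(orders$z_target)) orders$z_target <- NA_integer_
  stopifnot(all(orders$beta >= 0))
  structure(list(n_zoos = as.integer(n_zoos), regions = regions,
                 orders = orders, holding_prob = holding_prob,
                 abundance = abundance, zoo_intensity = zoo_intensity,
                 range_clustering = isTRUE(range_clustering),
                 range_sigma_km = range_sigma_km, seed = as.integer(seed)),
            class = "zoo_scenario")
}

#' @export
print.zoo_scenario <- function(x, ...) {
  cat(sprintf("<zoo_scenario> %d zoos in %d region(s), %d orders, seed %d\n",
              x$n_zoos, nrow(x$regions), nrow(x$orders), x$seed))
  invisible(x)
}

# degrees of latitude per km (spherical)
KM_PER_DEG <- 6371 * pi / 180

#' Generate zoo locations
#'
#' Scatters zoos around the scenario's region centres with Gaussian spread
#' (in km, converted to degrees; longitudinal spread is widened by
#' 1/cos(latitude)). Latitudes are clamped to (-89.9, 89.9) and longitudes
#' wrapped into \[-180, 180).
#'
#' @param scenario a `zoo_scenario`.
#' @param seed integer seed.
#' @return zoo data.frame (zoo_id, latitude, longitude).
#' @export
generate_zoos <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "zoo_scenario"))
  set.seed(seed)
  reg <- scenario$regions
  counts <- floor(reg$share * scenario$n_zoos)
  rem <- scenario$n_zoos - sum(counts)
  if (rem > 0) {
    frac <- reg$share * scenario$n_zoos - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  lat <- numeric(0); lon <- numeric(0)
  for (i in seq_len(nrow(reg))) {
    if (counts[i] == 0) next
    dlat <- stats::rnorm(counts[i], 0, reg$spread_km[i]) / KM_PER_DEG
    la <- pmin(pmax(reg$lat[i] + dlat, -89.9), 89.9)
    dlon <- stats::rnorm(counts[i], 0, reg$spread_km[i]) /
      (KM_PER_DEG * pmax(cos(la * pi / 180), 0.05))
    lo <- ((reg$lon[i] + dlon + 180) %% 360) - 180
    lat <- c(lat, la); lon <- c(lon, lo)
  }
  data.frame(zoo_id = sprintf("zoo_%03d", seq_len(scenario$n_zoos)),
             latitude = lat, longitude = lon, stringsAsFactors = FALSE)
}

#' Generate the world checklist and species pool
#'
#' Builds, for every order in the scenario, its `n_total` world species of
#' which exactly `n_threatened` are threatened. Threatened species receive
#' VU/EN/CR (probabilities 0.50/0.32/0.18), the remainder LC/NT/DD/EW
#' (0.82/0.10/0.06/0.02).
#'
#' @param scenario a `zoo_scenario`.
#' @param seed integer seed.
#' @return list with `checklist` (class, order, n_total, n_threatened) and
#'   `species_pool` (species_id, class_name, order_name, category,
#'   threatened) covering the whole world pool, not just held species.
#' @export
generate_checklist_and_species <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "zoo_scenario"))
  set.seed(seed)
  ords <- scenario$orders
  pools <- lapply(seq_len(nrow(ords)), function(i) {
    n <- ords$n_total[i]; m <- ords$n_threatened[i]
    thr <- rep(FALSE, n)
    if (m > 0) thr[sample.int(n, m)] <- TRUE
    cat_thr <- sample(c("VU", "EN", "CR"), n, replace = TRUE,
                      prob = c(0.50, 0.32, 0.18))
    cat_non <- sample(c("LC", "NT", "DD", "EW"), n, replace = TRUE,
                      prob = c(0.82, 0.10, 0.06, 0.02))
    data.frame(
      species_id = sprintf("%s_sp%05d", ords$order_name[i], seq_len(n)),
      class_name = ords$class_name[i],
      order_name = ords$order_name[i],
      category = ifelse(thr, cat_thr, cat_non),
      threatened = thr,
      stringsAsFactors = FALSE)
  })
  checklist <- ords[c("class_name", "order_name", "n_total", "n_threatened")]
  list(checklist = checklist, species_pool = do.call(rbind, pools))
}

# discretized Pareto abundance law; always >= 1 individual
draw_abundance <- function(n, abundance) {
  u <- stats::runif(n)
  tot <- round(abundance$scale * u^(-1 / abundance$shape))
  pmin(pmax(tot, 1), abundance$cap)
}

#' Sample zoo collections (holdings) from the world pool
#'
#' For each order, the number of species held in the network is either the
#' scenario's fixed `z_target` or Binomial(n_total, holding_prob); *which*
#' species are held is a weighted draw without replacement with weight
#' `beta` for threatened species and 1 otherwise (`beta = 1` reduces to
#' uniform random collection — the null hypothesis of the representation
#' test, under which the held threatened count is exactly hypergeometric).
#' Each held species then receives a global abundance from the heavy-tailed
#' law, split across `1 + Poisson(zoo_intensity * log10(1 + total))` holding
#' zoos (each with at least one individual). With `range_clustering`, a
#' species' holding zoos are drawn with distance-decay around a random
#' anchor zoo; otherwise uniformly.
#'
#' @param scenario a `zoo_scenario`.
#' @param zoos zoo table from [generate_zoos()].
#' @param species_pool world pool from [generate_checklist_and_species()].
#' @param seed integer seed.
#' @return list with `holdings` (zoo_id, species_id, count) and `truth`:
#'   per-order data.frame (order_name, z, w) of true held counts and a named
#'   vector `totals` of per-species global abundances.
#' @export
sample_zoo_collections <- function(scenario, zoos, species_pool,
                                   seed = scenario$seed) {
  stopifnot(inherits(scenario, "zoo_scenario"))
  set.seed(seed)
  ords <- scenario$orders
  n_zoos <- nrow(zoos)
  dmat <- if (scenario$range_clustering) pairwise_distance_matrix(zoos) else NULL

  held_rows <- list(); truth_rows <- list(); totals <- integer(0)
  for (i in seq_len(nrow(ords))) {
    pool <- species_pool[species_pool$order_name == ords$order_name[i], ]
    z <- if (!is.na(ords$z_target[i])) as.integer(ords$z_target[i])
         else stats::rbinom(1, ords$n_total[i], scenario$holding_prob)
    z <- min(z, ords$n_total[i])
    beta <- ords$beta[i]
    if (beta == 0 && z > sum(!pool$threatened)) {
      stop(sprintf("order %s: cannot hold %d species with beta = 0 and only %d non-threatened",
                   ords$order_name[i], z, sum(!pool$threatened)), call. = FALSE)
    }
    held <- if (z == 0) pool[0, ] else {
      wgt <- ifelse(pool$threatened, beta, 1)
      if (beta == 1) pool[sample.int(nrow(pool), z), ]
      else pool[sample.int(nrow(pool), z, prob = wgt), ]
    }
    truth_rows[[i]] <- data.frame(order_name = ords$order_name[i],
                                  z = nrow(held), w = sum(held$threatened),
                                  stringsAsFactors = FALSE)
    if (!nrow(held)) next
    tot <- draw_abundance(nrow(held), scenario$abundance)
    names(tot) <- held$species_id
    totals <- c(totals, tot)
    for (s in seq_len(nrow(held))) {
      k <- 1 + stats::rpois(1, scenario$zoo_intensity * log10(1 + tot[s]))
      k <- min(max(k, 1L), n_zoos, tot[s])
      zsel <- if (scenario$range_clustering && n_zoos > 1) {
        anchor <- sample.int(n_zoos, 1)
        p <- exp(-(dmat[anchor, ]^2) / (2 * scenario$range_sigma_km^2))
        sample.int(n_zoos, k, prob = p + 1e-12)
      } else sample.int(n_zoos, k)
      counts <- rep(1L, k)
      extra <- tot[s] - k
      if (extra > 0) {
        counts <- counts + stats::rmultinom(1, extra, rep(1 / k, k))[, 1]
      }
      held_rows[[length(held_rows) + 1L]] <-
        data.frame(zoo_id = zoos$zoo_id[zsel],
                   species_id = held$species_id[s],
                   count = as.integer(counts), stringsAsFactors = FALSE)
    }
  }
  holdings <- if (length(held_rows)) do.call(rbind, held_rows)
              else data.frame(zoo_id = character(0), species_id = character(0),
                              count = integer(0), stringsAsFactors = FALSE)
  rownames(holdings) <- NULL
  list(holdings = holdings,
       truth = list(orders = do.call(rbind, truth_rows), totals = totals))
}

#' Generate a complete validated synthetic dataset
#'
#' Composes [generate_zoos()], [generate_checklist_and_species()] and
#' [sample_zoo_collections()] and passes the result through
#' [validate_dataset()]. The dataset's species table contains only the
#' species actually held somewhere in the network, mirroring a real zoo
#' inventory extract.
#'
#' @param scenario a `zoo_scenario`.
#' @param seed integer seed (defaults to the scenario's own seed).
#' @return list with `dataset` (a `zoo_dataset`) and `truth` (ground-truth
#'   bookkeeping: per-order z and w, and per-species global totals).
#' @export
generate_dataset <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "zoo_scenario"))
  zoos <- generate_zoos(scenario, seed = seed)
  world <- generate_checklist_and_species(scenario, seed = seed + 1L)
  coll <- sample_zoo_collections(scenario, zoos, world$species_pool,
                                 seed = seed + 2L)
  held_ids <- unique(coll$holdings$species_id)
  species <- world$species_pool[world$species_pool$species_id %in% held_ids,
                                c("species_id", "class_name", "order_name",
                                  "category")]
  rownames(species) <- NULL
  dataset <- validate_dataset(zoos, species, coll$holdings, world$checklist)
  list(dataset = dataset, truth = coll$truth)
}
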