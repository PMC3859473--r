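#' Per-order species counts in the world and in zoos
#'
#' For a taxonomic order, collects the four counts that drive the
#' representation test: `n_total` species described worldwide, `n_threatened`
#' of them threatened (from the checklist), `n_in_zoos` distinct species of
#' the order held with at least one individual in the network, and
#' `n_threatened_in_zoos` the threatened subset of those (the observed value).
#'
#' @param dataset a `zoo_dataset`.
#' @param order_name taxonomic order, must be present in the checklist.
#' @return an object of class `order_counts`.
#' @export
order_counts <- function(dataset, order_name) {
  stopifnot(inherits(dataset, "zoo_dataset"))
  row <- dataset$checklist[dataset$checklist$order_name == order_name, , drop = FALSE]
  if (!nrow(row)) stop(sprintf("order '%s' not in checklist", order_name), call. = FALSE)
  held_ids <- unique(dataset$holdings$species_id)
  sp <- dataset$species
  held <- sp[sp$order_name == order_name & sp$species_id %in% held_ids, , drop = FALSE]
  out <- list(order_name = order_name,
              class_name = row$class_name[1],
              n_total = row$n_total[1],
              n_threatened = row$n_threatened[1],
              n_in_zoos = nrow(held),
              n_threatened_in_zoos = sum(is_threatened(held$category)))
  lo <- max(0L, out$n_in_zoos - (out$n_total - out$n_threatened))
  hi <- min(out$n_in_zoos, out$n_threatened)
  if (out$n_threatened_in_zoos < lo || out$n_threatened_in_zoos > hi) {
    stop(sprintf("order '%s': observed threatened count %d outside feasible [%d, %d]",
                 order_name, out$n_threatened_in_zoos, lo, hi), call. = FALSE)
  }
  structure(out, class = "order_counts")
}

as_order_counts <- function(n_total, n_threatened, n_in_zoos,
                            n_threatened_in_zoos = NA_integer_,
                            order_name = "order", class_name = "class") {
  stopifnot(n_threatened <= n_total, n_in_zoos <= n_total)
  structure(list(order_name = order_name, class_name = class_name,
                 n_total = as.integer(n_total),
                 n_threatened = as.integer(n_threatened),
                 n_in_zoos = as.integer(n_in_zoos),
                 n_threatened_in_zoos = as.integer(n_threatened_in_zoos)),
            class = "order_counts")
}

new_pmf <- function(counts, support, prob, engine, iterations = NA_integer_,
                    seed = NULL) {
  structure(list(order_name = counts$order_name, support = support,
                 prob = prob, engine = engine,
                 iterations = iterations, seed = seed),
            class = "representation_pmf")
}

#' Monte Carlo null distribution of threatened-species counts
#'
#' Simulates random collection: at each of `iterations` steps, draws
#' `n_in_zoos` species without replacement from a world pool of `n_total`
#' species containing `n_threatened` threatened ones, and tallies how many
#' threatened species were drawn. Normalized tallies form the empirical
#' probability mass function of the threatened count under the null
#' hypothesis of unplanned (random) collection.
#'
#' @param counts an `order_counts` object.
#' @param iterations number of Monte Carlo draws S (default 10,000).
#' @param seed optional integer seed for reproducibility.
#' @return a `representation_pmf` with support `0:min(n_in_zoos, n_threatened)`;
#'   every probability is a multiple of 1/S and the mass sums to 1.
#' @export
simulate_representation_pmf <- function(counts, iterations = 10000, seed = NULL) {
  stopifnot(inherits(counts, "order_counts"), iterations >= 1)
  n <- counts$n_total; m <- counts$n_threatened; z <- counts$n_in_zoos
  if (z > n) stop("more species in zoos than described worldwide", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  support <- 0:min(z, m)
  if (z == 0L || m == 0L) {
    prob <- c(1, rep(0, length(support) - 1L))
    return(new_pmf(counts, support, prob, "monte_carlo", iterations, seed))
  }
  # threatened species occupy pool positions 1..m; count how many are drawn
  draws <- vapply(seq_len(iterations),
                  function(s) sum(sample.int(n, z) <= m), integer(1))
  tally <- tabulate(draws + 1L, nbins = length(support))
  new_pmf(counts, support, tally / iterations, "monte_carlo", iterations, seed)
}

#' Exact hypergeometric null distribution
#'
#' Sampling species without replacement makes the null law of the threatened
#' count exactly hypergeometric; this is the analytic counterpart (and test
#' oracle) of [simulate_representation_pmf()]:
#' P(J = j) = C(m, j) C(n - m, z - j) / C(n, z) on the feasible range.
#'
#' @param counts an `order_counts` object.
#' @return a `representation_pmf` over the same support as the simulation.
#' @export
hypergeometric_pmf <- function(counts) {
  stopifnot(inherits(counts, "order_counts"))
  n <- counts$n_total; m <- counts$n_threatened; z <- counts$n_in_zoos
  if (z > n) stop("more species in zoos than described worldwide", call. = FALSE)
  support <- 0:min(z, m)
  prob <- stats::dhyper(support, m, n - m, z)
  new_pmf(counts, support, prob, "exact")
}

#' @export
print.representation_pmf <- function(x, ...) {
  cat(sprintf("<representation_pmf> order %s, engine %s, support 0..%d\n",
              x$order_name, x$engine, max(x$support)))
  invisible(x)
}

#' Mean of a null PMF
#' @param pmf a `representation_pmf`.
#' @return the expected threatened count under random collection.
#' @export
pmf_mean <- function(pmf) {
  stopifnot(inherits(pmf, "representation_pmf"))
  sum(pmf$support * pmf$prob)
}

#' Classify an order against its null distribution
#'
#' Computes the point probability of the observed threatened count, the two
#' cumulative tails, and classifies the order. Classification realizes the
#' 0.05 / 0.95 quantile rule through tails: `under_represented` iff
#' P(J <= observed) <= alpha, `over_represented` iff P(J >= observed) <=
#' alpha, else `indistinguishable` from random collection. Ties at the
#' quantile are inclusive. The identity
#' lower + upper - point = 1 always holds.
#'
#' @param pmf a `representation_pmf` (Monte Carlo or exact).
#' @param observed observed number of threatened species in zoos (w).
#' @param alpha significance level, default 0.05.
#' @return an object of class `representation_verdict`.
#' @export
classify_order <- function(pmf, observed, alpha = 0.05) {
  stopifnot(inherits(pmf, "representation_pmf"))
  if (!observed %in% pmf$support) {
    stop(sprintf("observed value %d outside PMF support 0..%d (data inconsistency)",
                 observed, max(pmf$support)), call. = FALSE)
  }
  point <- pmf$prob[pmf$support == observed]
  lower <- sum(pmf$prob[pmf$support <= observed])
  upper <- sum(pmf$prob[pmf$support >= observed])
  cls <- if (lower <= alpha) "under_represented"
         else if (upper <= alpha) "over_represented"
         else "indistinguishable"
  structure(list(order_name = pmf$order_name, observed = observed,
                 point_probability = point, lower_tail = lower,
                 upper_tail = upper, alpha = alpha, classification = cls),
            class = "representation_verdict")
}

#' @export
print.representation_verdict <- function(x, ...) {
  cat(sprintf("<verdict> %s: observed %d, P(J<=w)=%.4g, P(J>=w)=%.4g -> %s\n",
              x$order_name, x$observed, x$lower_tail, x$upper_tail,
              x$classification))
  invisible(x)
}

#' Representation test over all orders of a dataset
#'
#' Runs the per-order representation test for every checklist order and
#' returns one row per order. Orders with no species held in any zoo are
#' reported with classification `not_held` and NA tails. The expected
#' threatened count under the null (PMF mean) is included for
#' expected-versus-observed plots.
#'
#' @param dataset a `zoo_dataset`.
#' @param iterations Monte Carlo iterations S (ignored by the exact engine).
#' @param alpha significance level, default 0.05.
#' @param seed optional integer seed (Monte Carlo engine).
#' @param engine `"exact"` (default; the null is exactly hypergeometric) or
#'   `"monte_carlo"` (the resampling algorithm itself).
#' @return data.frame with columns order, class, n_total, n_threatened,
#'   n_in_zoos, w_observed, expected_w, point_prob, lower_tail, upper_tail,
#'   classification.
#' @export
representation_report <- function(dataset, iterations = 10000, alpha = 0.05,
                                  seed = NULL,
                                  engine = c("exact", "monte_carlo")) {
  stopifnot(inherits(dataset, "zoo_dataset"))
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  orders <- dataset$checklist$order_name
  rows <- lapply(orders, function(ord) {
    oc <- order_counts(dataset, ord)
    base <- data.frame(order = ord, class = oc$class_name,
                       n_total = oc$n_total, n_threatened = oc$n_threatened,
                       n_in_zoos = oc$n_in_zoos,
                       w_observed = oc$n_threatened_in_zoos,
                       stringsAsFactors = FALSE)
    if (oc$n_in_zoos == 0L) {
      base$expected_w <- 0
      base$point_prob <- NA_real_
      base$lower_tail <- NA_real_
      base$upper_tail <- NA_real_
      base$classification <- "not_held"
      return(base)
    }
    pmf <- if (engine == "exact") hypergeometric_pmf(oc)
           else simulate_representation_pmf(oc, iterations = iterations)
    v <- classify_order(pmf, oc$n_threatened_in_zoos, alpha = alpha)
    base$expected_w <- pmf_mean(pmf)
    base$point_prob <- v$point_probability
    base$lower_tail <- v$lower_tail
    base$upper_tail <- v$upper_tail
    base$classification <- v$classification
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
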