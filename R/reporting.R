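#' Percentage with half-away-from-zero rounding
#'
#' Computes 100 * numerator / denominator and rounds half away from zero
#' (the convention of printed conservation tables, unlike base R's
#' round-half-even).
#'
#' @param numerator,denominator counts; denominator must be positive.
#' @param decimals decimal places (default 1).
#' @return rounded percentage.
#' @export
#' @examples
#' percent_threatened(178, 445)      # 40.0
#' percent_threatened(15, 56, 0)     # 27
percent_threatened <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) stop("denominator must be positive", call. = FALSE)
  x <- 100 * numerator / denominator
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Species counts by class and Red List category
#'
#' Counts distinct held species per taxonomic class and IUCN category, with
#' a Total row, total-species column, threatened count (VU + EN + CR) and
#' threatened percentage of the class's held species (1 decimal,
#' half-away-from-zero; NA for empty classes).
#'
#' @param dataset a `zoo_dataset`.
#' @return data.frame with rows = classes plus "Total", columns = the seven
#'   categories, total_species, threatened, threatened_pct.
#' @export
summarize_by_category <- function(dataset) {
  stopifnot(inherits(dataset, "zoo_dataset"))
  sp <- dataset$species
  classes <- sort(unique(sp$class_name))
  mk_row <- function(label, sub) {
    counts <- vapply(iucn_categories,
                     function(cc) sum(sub$category == cc), integer(1))
    total <- nrow(sub)
    thr <- sum(counts[threatened_categories])
    row <- as.data.frame(as.list(counts), stringsAsFactors = FALSE)
    row <- cbind(data.frame(class = label, stringsAsFactors = FALSE), row)
    row$total_species <- total
    row$threatened <- thr
    row$threatened_pct <- if (total > 0) percent_threatened(thr, total, 1) else NA_real_
    row
  }
  rows <- lapply(classes, function(cl) mk_row(cl, sp[sp$class_name == cl, ]))
  rows[[length(rows) + 1L]] <- mk_row("Total", sp)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Species counts by class, population band and category
#'
#' Assigns every held species to exactly one population-size band by its
#' network-wide total, using half-open intervals (lower, upper], and counts
#' species per class x band x Red List category. Band edges default to
#' 0, 50, 100, 250, 500, 1,000, 2,000, Inf. Note: unlike some published
#' tables where the smallest band is printed empty, totals of 1-50
#' individuals genuinely land in the "0-50" band here.
#'
#' @param dataset a `zoo_dataset`.
#' @param band_edges strictly increasing numeric vector of band boundaries;
#'   the first edge is exclusive, so it should be 0 (all totals are >= 1).
#' @return data.frame with columns class, band, the seven categories.
#' @export
summarize_population_thresholds <- function(dataset,
                                            band_edges = c(0, 50, 100, 250,
                                                           500, 1000, 2000,
                                                           Inf)) {
  stopifnot(inherits(dataset, "zoo_dataset"), all(diff(band_edges) > 0))
  totals <- species_global_totals(dataset)
  sp <- dataset$species[dataset$species$species_id %in% names(totals), ]
  tot <- totals[sp$species_id]
  n_band <- length(band_edges) - 1L
  labels <- vapply(seq_len(n_band), function(i) {
    if (is.infinite(band_edges[i + 1])) sprintf(">%g", band_edges[i])
    else sprintf("%g-%g", band_edges[i], band_edges[i + 1])
  }, character(1))
  band <- cut(tot, breaks = band_edges, labels = labels, right = TRUE)
  if (anyNA(band)) {
    stop("some species totals fall outside the band edges", call. = FALSE)
  }
  classes <- sort(unique(sp$class_name))
  rows <- list()
  for (cl in classes) {
    for (b in labels) {
      sub <- sp[sp$class_name == cl & band == b, ]
      counts <- vapply(iucn_categories,
                       function(cc) sum(sub$category == cc), integer(1))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(class = cl, band = b, stringsAsFactors = FALSE),
        as.data.frame(as.list(counts), stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
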