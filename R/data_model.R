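#' IUCN Red List category codes
#'
#' The seven Red List categories handled by the package, in conventional
#' order of increasing extinction risk (DD is listed first as "unassessable").
#' A species is *threatened* iff its category is VU, EN or CR.
#'
#' @format Character vector of length 7.
#' @export
iucn_categories <- c("DD", "LC", "NT", "VU", "EN", "CR", "EW")

#' Threatened Red List categories
#' @format Character vector: VU, EN, CR.
#' @export
threatened_categories <- c("VU", "EN", "CR")

#' Is a Red List category threatened?
#'
#' @param category character vector of IUCN category codes (any case).
#' @return logical vector; TRUE iff the code is VU, EN or CR.
#' @export
#' @examples
#' is_threatened(c("LC", "vu", "CR"))
is_threatened <- function(category) {
  toupper(category) %in% threatened_categories
}

# ---- internal validation helpers ---------------------------------------

stop_report <- function(errors, context) {
  if (length(errors)) {
    stop(sprintf("%s: %d problem(s) found:\n  - %s",
                 context, length(errors), paste(errors, collapse = "\n  - ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("'%s': missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df[required]
}

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  strip.white = TRUE)
}

#' Read a zoo registry table
#'
#' Expects a CSV with header `zoo_id,latitude,longitude`. Coordinates are in
#' decimal degrees, latitude in \[-90, 90\], longitude in \[-180, 180).
#' Row order is preserved; duplicate ids and out-of-range or unparsable
#' coordinates are validation errors naming the offending row.
#'
#' @param path path to the CSV file.
#' @return data.frame with columns zoo_id (character), latitude, longitude.
#' @export
read_zoo_table <- function(path) {
  df <- read_csv_strict(path)
  df <- check_columns(df, c("zoo_id", "latitude", "longitude"), path)
  df$zoo_id <- as.character(df$zoo_id)
  errors <- character(0)
  for (col in c("latitude", "longitude")) {
    suppressWarnings(v <- as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      errors <- c(errors, sprintf("row %d: unparsable %s '%s'",
                                  bad, col, df[[col]][bad]))
    }
    df[[col]] <- v
  }
  bad_lat <- which(!is.na(df$latitude) & abs(df$latitude) > 90)
  if (length(bad_lat)) {
    errors <- c(errors, sprintf("row %d: latitude %g out of [-90, 90]",
                                bad_lat, df$latitude[bad_lat]))
  }
  bad_lon <- which(!is.na(df$longitude) &
                     (df$longitude < -180 | df$longitude >= 180))
  if (length(bad_lon)) {
    errors <- c(errors, sprintf("row %d: longitude %g out of [-180, 180)",
                                bad_lon, df$longitude[bad_lon]))
  }
  dup <- unique(df$zoo_id[duplicated(df$zoo_id)])
  if (length(dup)) {
    errors <- c(errors, sprintf("duplicate zoo_id: %s",
                                paste(dup, collapse = ", ")))
  }
  stop_report(errors, sprintf("invalid zoo table '%s'", path))
  df
}

#' Read a species table
#'
#' Expects a CSV with header `species_id,class_name,order_name,category`,
#' where category is one of DD, LC, NT, VU, EN, CR, EW (any case; normalized
#' to upper case on read).
#'
#' @param path path to the CSV file.
#' @return data.frame with character columns and normalized categories.
#' @export
read_species_table <- function(path) {
  df <- read_csv_strict(path)
  df <- check_columns(df, c("species_id", "class_name", "order_name", "category"), path)
  for (col in names(df)) df[[col]] <- as.character(df[[col]])
  df$category <- toupper(df$category)
  errors <- character(0)
  bad <- which(!df$category %in% iucn_categories)
  if (length(bad)) {
    errors <- c(errors, sprintf("row %d: unknown IUCN category '%s'",
                                bad, df$category[bad]))
  }
  dup <- unique(df$species_id[duplicated(df$species_id)])
  if (length(dup)) {
    errors <- c(errors, sprintf("duplicate species_id: %s",
                                paste(dup, collapse = ", ")))
  }
  stop_report(errors, sprintf("invalid species table '%s'", path))
  df
}

#' Read a holdings table
#'
#' Expects a CSV with header `zoo_id,species_id,count` giving the number of
#' living individuals of each species in each zoo.
#'
#' @param path path to the CSV file.
#' @return data.frame with zoo_id, species_id (character) and integer count.
#' @export
read_holdings_table <- function(path) {
  df <- read_csv_strict(path)
  df <- check_columns(df, c("zoo_id", "species_id", "count"), path)
  df$zoo_id <- as.character(df$zoo_id)
  df$species_id <- as.character(df$species_id)
  errors <- character(0)
  suppressWarnings(v <- as.numeric(df$count))
  bad <- which(is.na(v) | v < 0 | v != floor(v))
  if (length(bad)) {
    errors <- c(errors, sprintf("row %d: count '%s' is not a non-negative integer",
                                bad, df$count[bad]))
  }
  df$count <- as.integer(v)
  key <- paste(df$zoo_id, df$species_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    errors <- c(errors, sprintf("row %d: duplicate (zoo_id, species_id) pair (%s, %s)",
                                dup, df$zoo_id[dup], df$species_id[dup]))
  }
  stop_report(errors, sprintf("invalid holdings table '%s'", path))
  df
}

#' Read a world checklist table
#'
#' Expects a CSV with header `class_name,order_name,n_total,n_threatened`:
#' for every taxonomic order, the number of described species worldwide and
#' how many of them are threatened. This is the sampling universe for the
#' representation test.
#'
#' @param path path to the CSV file.
#' @return data.frame with class_name, order_name, n_total, n_threatened.
#' @export
read_checklist_table <- function(path) {
  df <- read_csv_strict(path)
  df <- check_columns(df, c("class_name", "order_name", "n_total", "n_threatened"), path)
  df$class_name <- as.character(df$class_name)
  df$order_name <- as.character(df$order_name)
  errors <- character(0)
  for (col in c("n_total", "n_threatened")) {
    suppressWarnings(v <- as.numeric(df[[col]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      errors <- c(errors, sprintf("row %d: %s '%s' is not a non-negative integer",
                                  bad, col, df[[col]][bad]))
    }
    df[[col]] <- as.integer(v)
  }
  bad <- which(df$n_threatened > df$n_total)
  if (length(bad)) {
    errors <- c(errors, sprintf("row %d: n_threatened (%d) exceeds n_total (%d)",
                                bad, df$n_threatened[bad], df$n_total[bad]))
  }
  dup <- which(duplicated(paste(df$class_name, df$order_name, sep = "\r")))
  if (length(dup)) {
    errors <- c(errors, sprintf("row %d: duplicate (class, order) (%s, %s)",
                                dup, df$class_name[dup], df$order_name[dup]))
  }
  stop_report(errors, sprintf("invalid checklist table '%s'", path))
  df
}

#' Validate and assemble a zoo-network dataset
#'
#' Cross-checks the four tables and assembles them into a `zoo_dataset`
#' object used by all analyses. Holdings rows with count 0 are dropped with
#' a warning (counts are living individuals). All invariant violations are
#' aggregated into a single error report.
#'
#' Checked invariants: every species order appears in the checklist; every
#' holding references a known zoo and species; for every order, the number of
#' distinct held species does not exceed the checklist total, and held
#' threatened species do not exceed the checklist threatened count.
#'
#' @param zoos,species,holdings,checklist data frames as returned by the
#'   `read_*_table` readers.
#' @return an object of class `zoo_dataset`: a list with elements `zoos`,
#'   `species`, `holdings`, `checklist`.
#' @export
validate_dataset <- function(zoos, species, holdings, checklist) {
  errors <- character(0)

  zero <- holdings$count == 0
  if (any(zero)) {
    warning(sprintf("dropping %d holdings row(s) with count 0", sum(zero)),
            call. = FALSE)
    holdings <- holdings[!zero, , drop = FALSE]
    rownames(holdings) <- NULL
  }

  bad <- setdiff(holdings$zoo_id, zoos$zoo_id)
  if (length(bad)) {
    errors <- c(errors, sprintf("holdings reference unknown zoo_id: %s",
                                paste(bad, collapse = ", ")))
  }
  bad <- setdiff(holdings$species_id, species$species_id)
  if (length(bad)) {
    errors <- c(errors, sprintf("holdings reference unknown species_id: %s",
                                paste(bad, collapse = ", ")))
  }

  key_s <- paste(species$class_name, species$order_name, sep = "\r")
  key_c <- paste(checklist$class_name, checklist$order_name, sep = "\r")
  miss <- unique(species$order_name[!key_s %in% key_c])
  if (length(miss)) {
    errors <- c(errors, sprintf("species order(s) absent from checklist: %s",
                                paste(miss, collapse = ", ")))
  }

  # per-order held counts must be feasible w.r.t. the world checklist
  held_ids <- unique(holdings$species_id)
  held <- species[species$species_id %in% held_ids, , drop = FALSE]
  if (nrow(held) && !length(errors)) {
    z_i <- tapply(held$species_id, held$order_name, length)
    w_i <- tapply(is_threatened(held$category), held$order_name, sum)
    for (ord in names(z_i)) {
      row <- checklist[checklist$order_name == ord, , drop = FALSE]
      if (!nrow(row)) next
      if (z_i[[ord]] > row$n_total[1]) {
        errors <- c(errors, sprintf(
          "order %s: %d species held in zoos but only %d described worldwide",
          ord, z_i[[ord]], row$n_total[1]))
      }
      if (w_i[[ord]] > row$n_threatened[1]) {
        errors <- c(errors, sprintf(
          "order %s: %d threatened species held but only %d threatened worldwide",
          ord, w_i[[ord]], row$n_threatened[1]))
      }
    }
  }

  stop_report(errors, "dataset validation failed")
  structure(list(zoos = zoos, species = species,
                 holdings = holdings, checklist = checklist),
            class = "zoo_dataset")
}

#' @export
print.zoo_dataset <- function(x, ...) {
  cat(sprintf("<zoo_dataset> %d zoos, %d species, %d holdings rows, %d checklist orders\n",
              nrow(x$zoos), nrow(x$species), nrow(x$holdings), nrow(x$checklist)))
  cls <- sort(unique(x$species$class_name))
  for (cl in cls) {
    sp <- x$species[x$species$class_name == cl, ]
    cat(sprintf("  %-12s %4d species (%d threatened)\n",
                cl, nrow(sp), sum(is_threatened(sp$category))))
  }
  invisible(x)
}

#' Read a dataset directory
#'
#' Convenience wrapper: reads `zoos.csv`, `species.csv`, `holdings.csv` and
#' `checklist.csv` from a directory and validates them.
#'
#' @param dir directory containing the four CSV files.
#' @return a `zoo_dataset`.
#' @export
read_dataset <- function(dir) {
  validate_dataset(
    zoos = read_zoo_table(file.path(dir, "zoos.csv")),
    species = read_species_table(file.path(dir, "species.csv")),
    holdings = read_holdings_table(file.path(dir, "holdings.csv")),
    checklist = read_checklist_table(file.path(dir, "checklist.csv"))
  )
}

#' Write a dataset directory
#'
#' Writes the four tables of a `zoo_dataset` as CSV files into `dir`
#' (created if needed). Inverse of [read_dataset()] up to float formatting.
#'
#' @param dataset a `zoo_dataset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "zoo_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(dataset$zoos, file.path(dir, "zoos.csv"), row.names = FALSE)
  utils::write.csv(dataset$species, file.path(dir, "species.csv"), row.names = FALSE)
  utils::write.csv(dataset$holdings, file.path(dir, "holdings.csv"), row.names = FALSE)
  utils::write.csv(dataset$checklist, file.path(dir, "checklist.csv"), row.names = FALSE)
  invisible(dir)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6,371 km. Vectorized over all
#' four coordinate arguments. Symmetric, non-negative, and zero iff the two
#' points coincide.
#'
#' @param lat1,lon1 coordinates of the first point(s), decimal degrees.
#' @param lat2,lon2 coordinates of the second point(s), decimal degrees.
#' @return distance(s) in km.
#' @export
#' @examples
#' haversine_km(0, 0, 0, 180)  # half great circle, ~20015 km
haversine_km <- function(lat1, lon1, lat2, lon2) {
  R <- 6371
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad; phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * R * asin(sqrt(a))
}
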