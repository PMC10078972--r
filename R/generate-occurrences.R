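#' Generate a synthetic occurrence table with known truth
#'
#' Draws occurrence records for each species from a species-specific range
#' centre inside the toy world, attaches the true country, biome, realm and
#' climate values at each point, and then corrupts coordinates at the given
#' rates: `swap` (lat/lon interchanged), `sign_flip` (latitude sign
#' reversed), `offshore` (point displaced into the ocean, unrepairable).
#' Optionally a `missing` rate blanks one random environmental variable per
#' affected record. The uncorrupted truth is retained as a sidecar
#' (attribute `"truth"`, see [occurrence_truth()]) so downstream cleaning
#' can be checked record by record.
#'
#' @param species character vector of species labels (e.g. tree tip labels).
#' @param world a `world_spec` from [world_default()].
#' @param n_per_species records per species: a single count, a vector
#'   (recycled across species), or a function of the number of species
#'   returning counts.
#' @param error_rates list with elements `swap`, `sign_flip`, `offshore`
#'   (and optionally `missing`), each a rate in `[0, 1]`; their sum must
#'   not exceed 1.
#' @param spread standard deviation (degrees) of records around the
#'   species' range centre.
#' @param seed integer seed.
#' @return a data frame with columns `record_id`, `species`, `lat`, `lon`,
#'   `country`, `biome`, `realm` and the 36 [env_variables()], with the
#'   truth sidecar as attribute `"truth"`.
#' @export
generate_occurrences <- function(species, world = world_default(),
                                 n_per_species = 20,
                                 error_rates = list(swap = 0, sign_flip = 0,
                                                    offshore = 0),
                                 spread = 3, seed = NULL) {
  if (length(species) == 0L) stop("species list is empty")
  rates <- c(swap = 0, sign_flip = 0, offshore = 0, missing = 0)
  rates[names(error_rates)] <- unlist(error_rates)
  if (any(rates < 0 | rates > 1) || sum(rates[1:3]) > 1) {
    stop("error rates must lie in [0, 1] and sum to at most 1")
  }
  counts <- if (is.function(n_per_species)) {
    n_per_species(length(species))
  } else {
    rep_len(n_per_species, length(species))
  }
  stopifnot(all(counts >= 1))

  with_seed(seed, {
    co <- world$countries
    area <- (co$lon1 - co$lon0) * (co$lat1 - co$lat0)
    sp_country <- sample.int(nrow(co), length(species), replace = TRUE,
                             prob = area / sum(area))
    centre_lon <- runif(length(species), co$lon0[sp_country],
                        co$lon1[sp_country])
    centre_lat <- runif(length(species), co$lat0[sp_country],
                        co$lat1[sp_country])

    rec <- vector("list", length(species))
    for (s in seq_along(species)) {
      n <- counts[s]
      lat <- numeric(n); lon <- numeric(n)
      for (r in seq_len(n)) {
        for (try in seq_len(100L)) {
          la <- centre_lat[s] + rnorm(1L, sd = spread)
          lo <- centre_lon[s] + rnorm(1L, sd = spread)
          if (world_on_land(world, la, lo)) break
          la <- centre_lat[s]; lo <- centre_lon[s]
        }
        lat[r] <- la; lon[r] <- lo
      }
      rec[[s]] <- data.frame(species = species[s], lat = lat, lon = lon,
                             stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, rec)
    rec <- cbind(record_id = seq_len(nrow(rec)), rec)

    rec$country <- world_country(world, rec$lat, rec$lon)
    rec$biome <- world_biome(world, rec$lat, rec$lon)
    rec$realm <- world_realm(world, rec$lat, rec$lon)
    rec <- cbind(rec, world$climate(rec$lat, rec$lon))

    # corrupt coordinates, keeping the truth aside
    u <- runif(nrow(rec))
    corruption <- rep("none", nrow(rec))
    corruption[u < rates["swap"]] <- "swap"
    corruption[u >= rates["swap"] &
                 u < rates["swap"] + rates["sign_flip"]] <- "sign_flip"
    corruption[u >= rates["swap"] + rates["sign_flip"] &
                 u < sum(rates[1:3])] <- "offshore"
    truth <- data.frame(record_id = rec$record_id, true_lat = rec$lat,
                        true_lon = rec$lon, corruption = corruption,
                        stringsAsFactors = FALSE)
    sw <- corruption == "swap"
    tmp <- rec$lat[sw]; rec$lat[sw] <- rec$lon[sw]; rec$lon[sw] <- tmp
    fl <- corruption == "sign_flip"
    rec$lat[fl] <- -rec$lat[fl]
    off <- corruption == "offshore"
    rec$lon[off] <- 0                     # open ocean in this world

    if (rates["missing"] > 0) {
      vars <- env_variables()
      hit <- which(runif(nrow(rec)) < rates["missing"])
      for (i in hit) rec[i, sample(vars, 1L)] <- NA_real_
    }

    attr(rec, "truth") <- truth
    rec
  })
}

#' Truth sidecar of a synthetic occurrence table
#'
#' @param records a table from [generate_occurrences()].
#' @return data frame with `record_id`, `true_lat`, `true_lon`,
#'   `corruption`.
#' @export
occurrence_truth <- function(records) {
  tr <- attr(records, "truth")
  if (is.null(tr)) stop("records carry no truth sidecar")
  tr
}

#' Write / read occurrence tables as CSV with a JSON truth sidecar
#'
#' @param records occurrence table.
#' @param path CSV path; the truth sidecar (if present) is written next to
#'   it as `<path>.truth.json`.
#' @return `write_occurrences()`: the path, invisibly. `read_occurrences()`:
#'   the table, with the sidecar re-attached when found.
#' @export
write_occurrences <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  tr <- attr(records, "truth")
  if (!is.null(tr)) {
    jsonlite::write_json(tr, paste0(path, ".truth.json"), digits = NA)
  }
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar)) {
    attr(rec, "truth") <- as.data.frame(jsonlite::read_json(
      sidecar, simplifyVector = TRUE))
  }
  rec
}
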