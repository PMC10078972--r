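#' Validate and repair occurrence coordinates against the reported country
#'
#' Each record's coordinates are tried in a fixed order of eight variants:
#' as given, latitude sign flipped, longitude sign flipped, both signs
#' flipped, and the same four after interchanging latitude and longitude.
#' The first variant that lies on land and within `tolerance` degrees of
#' the reported country is accepted (with the repaired coordinates
#' substituted); otherwise the record is rejected with a reason code:
#' `unknown-country` (reported country not in the world),
#' `off-land` (no variant on land) or `wrong-country` (on land only in
#' the wrong place).
#'
#' @param records occurrence table with `record_id`, `species`, `lat`,
#'   `lon`, `country` columns.
#' @param world a `world_spec`.
#' @param tolerance acceptance buffer around the reported country, in
#'   degrees.
#' @return list with `records` (accepted rows, coordinates repaired, plus
#'   a `repair` column naming the variant used) and `rejected` (data frame
#'   `record_id`, `species`, `reason`).
#' @export
validate_records <- function(records, world, tolerance = 1) {
  stopifnot(all(c("record_id", "species", "lat", "lon", "country")
                %in% names(records)))
  variants <- list(
    as_given  = function(la, lo) c(la, lo),
    lat_flip  = function(la, lo) c(-la, lo),
    lon_flip  = function(la, lo) c(la, -lo),
    both_flip = function(la, lo) c(-la, -lo),
    swap           = function(la, lo) c(lo, la),
    swap_lat_flip  = function(la, lo) c(-lo, la),
    swap_lon_flip  = function(la, lo) c(lo, -la),
    swap_both_flip = function(la, lo) c(-lo, -la))

  n <- nrow(records)
  keep <- logical(n)
  reason <- rep(NA_character_, n)
  repair <- rep(NA_character_, n)
  lat_new <- records$lat
  lon_new <- records$lon
  known <- records$country %in% world$countries$name

  for (i in seq_len(n)) {
    if (!known[i]) {
      reason[i] <- "unknown-country"
      next
    }
    any_land <- FALSE
    for (vn in names(variants)) {
      pt <- variants[[vn]](records$lat[i], records$lon[i])
      if (!world_on_land(world, pt[1], pt[2])) next
      any_land <- TRUE
      if (country_distance(world, records$country[i], pt[1], pt[2])
          <= tolerance) {
        keep[i] <- TRUE
        repair[i] <- vn
        lat_new[i] <- pt[1]; lon_new[i] <- pt[2]
        break
      }
    }
    if (!keep[i]) reason[i] <- if (any_land) "wrong-country" else "off-land"
  }

  accepted <- records[keep, , drop = FALSE]
  accepted$lat <- lat_new[keep]
  accepted$lon <- lon_new[keep]
  accepted$repair <- repair[keep]
  rejected <- data.frame(record_id = records$record_id[!keep],
                         species = records$species[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  list(records = accepted, rejected = rejected)
}

#' Retain records with unique coordinates per species
#'
#' Keeps the first record for every distinct (species, latitude,
#' longitude) triple.
#'
#' @param records validated occurrence table.
#' @return the table with duplicate-coordinate records removed.
#' @export
dedupe_unique <- function(records) {
  records[!duplicated(records[c("species", "lat", "lon")]), , drop = FALSE]
}

#' Drop records missing any required environmental variable
#'
#' @param records occurrence table.
#' @param required variable names that must all be non-missing.
#' @return the complete-case table; the number of dropped rows is attached
#'   as attribute `"n_dropped"` and reported via `message()`.
#' @export
filter_complete <- function(records, required = env_variables()) {
  stopifnot(length(required) > 0, all(required %in% names(records)))
  ok <- !Reduce(`|`, lapply(records[required], is.na))
  out <- records[ok, , drop = FALSE]
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(sprintf("filter_complete: dropped %d record(s) with missing values",
                    n_dropped))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Per-species climatic medians and biome/realm occupancy proportions
#'
#' For each species, computes the median of every environmental variable
#' over its (validated, deduplicated, complete) records — with
#' temperature-family bioclim variables divided by 10 so they are reported
#' in degrees Celsius — and the proportion of unique records falling in
#' each biome and each realm. Species with a single record are retained
#' (their median is that record's value). Expected species with zero
#' surviving records are omitted with a message.
#'
#' @param records cleaned occurrence table.
#' @param temperature_vars variables to divide by 10 before reporting
#'   (default [temperature_variables()]).
#' @param variables environmental variables to summarize.
#' @param species optional vector of expected species, used only to report
#'   which of them ended up with no records.
#' @return class `species_summary`: list with `climate` (data frame:
#'   species, n_records, one column per variable), `biome` and `realm`
#'   (long data frames: species, label, proportion).
#' @export
summarize_species <- function(records,
                              temperature_vars = temperature_variables(),
                              variables = env_variables(),
                              species = NULL) {
  stopifnot(all(variables %in% names(records)))
  if (!is.null(species)) {
    missing_sp <- setdiff(species, unique(records$species))
    if (length(missing_sp) > 0) {
      message(sprintf("summarize_species: %d species omitted (no records): %s",
                      length(missing_sp),
                      paste(missing_sp, collapse = ", ")))
    }
  }
  sp <- split(records, records$species)
  climate <- do.call(rbind, lapply(names(sp), function(nm) {
    med <- vapply(variables, function(v) median(sp[[nm]][[v]]), numeric(1))
    med[intersect(temperature_vars, variables)] <-
      med[intersect(temperature_vars, variables)] / 10
    cbind(data.frame(species = nm, n_records = nrow(sp[[nm]]),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(med)))
  }))
  rownames(climate) <- NULL

  prop_table <- function(col) {
    out <- do.call(rbind, lapply(names(sp), function(nm) {
      tab <- table(sp[[nm]][[col]])
      data.frame(species = nm, label = names(tab),
                 proportion = as.numeric(tab) / sum(tab),
                 stringsAsFactors = FALSE)
    }))
    names(out)[2] <- col
    rownames(out) <- NULL
    out
  }

  structure(list(climate = climate,
                 biome = prop_table("biome"),
                 realm = prop_table("realm")),
            class = "species_summary")
}

#' Full occurrence cleaning pipeline
#'
#' Runs validation/repair, unique-coordinate deduplication, complete-case
#' filtering and per-species summarization in order.
#'
#' @inheritParams validate_records
#' @inheritParams filter_complete
#' @inheritParams summarize_species
#' @return list with `summary` (a `species_summary`), `records` (the
#'   cleaned table), `rejected` and `n_dropped`.
#' @export
prep_occurrences <- function(records, world, tolerance = 1,
                             required = env_variables(),
                             temperature_vars = temperature_variables(),
                             species = NULL) {
  val <- validate_records(records, world, tolerance)
  ded <- dedupe_unique(val$records)
  com <- filter_complete(ded, required)
  list(summary = summarize_species(com, temperature_vars,
                                   variables = required, species = species),
       records = com,
       rejected = val$rejected,
       n_dropped = attr(com, "n_dropped"))
}
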