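#' Olson-style biome labels
#'
#' The 14 terrestrial biome labels used throughout the package for biome
#' tagging and canopy coding.
#' @export
olson_biomes <- c(
  "Tropical & Subtropical Moist Broadleaf Forests",
  "Tropical & Subtropical Dry Broadleaf Forests",
  "Tropical & Subtropical Coniferous Forests",
  "Temperate Broadleaf & Mixed Forests",
  "Temperate Conifer Forests",
  "Boreal Forests/Taiga",
  "Tropical & Subtropical Grasslands, Savannas & Shrublands",
  "Temperate Grasslands, Savannas & Shrublands",
  "Flooded Grasslands & Savannas",
  "Montane Grasslands & Shrublands",
  "Tundra",
  "Mediterranean Forests, Woodlands & Scrub",
  "Deserts & Xeric Shrublands",
  "Mangroves")

#' Names of the environmental variables attached to occurrence records
#'
#' Nineteen bioclimatic variables, net primary productivity, potential
#' evapotranspiration, elevation, and fourteen topsoil variables
#' (36 in total).
#' @return character vector of 36 column names.
#' @export
env_variables <- function() {
  c(paste0("BIO", 1:19), "npp", "pet", "elev",
    paste0("soil_", c("gravel", "sand", "silt", "clay", "bulk_density",
                      "org_carbon", "ph", "cec", "bs", "teb", "caco3",
                      "caso4", "esp", "ece")))
}

#' Temperature-family bioclim variables stored in tenths of a degree
#'
#' BIO1-BIO11 except BIO3 (an index) and BIO4 (a standard deviation x 100,
#' left on its native scale). These are the variables divided by 10 when
#' per-species medians are reported in degrees Celsius. Overridable in
#' [summarize_species()].
#' @return character vector of variable names.
#' @export
temperature_variables <- function() {
  paste0("BIO", c(1, 2, 5, 6, 7, 8, 9, 10, 11))
}

#' A deterministic toy world for synthetic occurrence data
#'
#' Builds a "world" of named axis-aligned rectangular countries (their
#' union is the land mask), each carrying one biogeographic realm and a
#' stack of latitudinal biome bands, plus smooth deterministic climate
#' fields for all 36 environmental variables (temperature-family
#' variables in tenths of degrees, as in raw bioclim layers). All land
#' lies in lon [-150, -61], lat [5, 45]: the latitude band, its negation,
#' the longitude band and its negation are pairwise disjoint, so any
#' lat/lon swap or sign flip of a land point leaves land. Coordinate
#' corruption is therefore always detectable, and the first repairing
#' variant in the fixed search order is the true one.
#'
#' @return an object of class `world_spec` with elements `bbox`,
#'   `countries` (data frame: name, lon0, lon1, lat0, lat1, realm),
#'   `biomes` (data frame: country, lat0, lat1, biome) and `climate`
#'   (vectorized function of `lat`, `lon` returning the 36 variables).
#' @export
world_default <- function() {
  countries <- data.frame(
    name = c("Aridia", "Silvania", "Mangrovia",
             "Borealia", "Steppia", "Montania"),
    lon0 = c(-150, -112, -84, -150, -112, -84),
    lon1 = c(-118, -89, -61, -118, -89, -61),
    lat0 = c(5, 5, 5, 28, 28, 28),
    lat1 = c(22, 22, 22, 45, 45, 45),
    realm = c("Neotropic", "Afrotropic", "Australasia",
              "Nearctic", "Palearctic", "Indomalaya"),
    stringsAsFactors = FALSE)

  band <- function(country, lat0, lat1, biome) {
    data.frame(country = country, lat0 = lat0, lat1 = lat1, biome = biome,
               stringsAsFactors = FALSE)
  }
  biomes <- rbind(
    # tropical row: deserts dominate Aridia, forests Silvania,
    # coasts/mangroves Mangrovia
    band("Aridia", 5, 12, "Deserts & Xeric Shrublands"),
    band("Aridia", 12, 18,
         "Tropical & Subtropical Grasslands, Savannas & Shrublands"),
    band("Aridia", 18, 22, "Tropical & Subtropical Dry Broadleaf Forests"),
    band("Silvania", 5, 14, "Tropical & Subtropical Moist Broadleaf Forests"),
    band("Silvania", 14, 18, "Tropical & Subtropical Coniferous Forests"),
    band("Silvania", 18, 22,
         "Tropical & Subtropical Grasslands, Savannas & Shrublands"),
    band("Mangrovia", 5, 8, "Mangroves"),
    band("Mangrovia", 8, 16, "Tropical & Subtropical Moist Broadleaf Forests"),
    band("Mangrovia", 16, 19, "Flooded Grasslands & Savannas"),
    band("Mangrovia", 19, 22, "Montane Grasslands & Shrublands"),
    # temperate row
    band("Borealia", 28, 33, "Temperate Broadleaf & Mixed Forests"),
    band("Borealia", 33, 38, "Temperate Conifer Forests"),
    band("Borealia", 38, 43, "Boreal Forests/Taiga"),
    band("Borealia", 43, 45, "Tundra"),
    band("Steppia", 28, 32, "Mediterranean Forests, Woodlands & Scrub"),
    band("Steppia", 32, 38, "Temperate Grasslands, Savannas & Shrublands"),
    band("Steppia", 38, 42, "Deserts & Xeric Shrublands"),
    band("Steppia", 42, 45, "Temperate Conifer Forests"),
    band("Montania", 28, 33, "Mediterranean Forests, Woodlands & Scrub"),
    band("Montania", 33, 39, "Temperate Broadleaf & Mixed Forests"),
    band("Montania", 39, 43, "Montane Grasslands & Shrublands"),
    band("Montania", 43, 45, "Tundra"))

  structure(list(bbox = c(lon0 = -180, lon1 = 180, lat0 = -90, lat1 = 90),
                 countries = countries, biomes = biomes,
                 climate = toy_climate),
            class = "world_spec")
}

# Smooth deterministic climate fields. Temperature-family bioclim values
# are returned in tenths of degrees C, mirroring raw bioclim rasters.
toy_climate <- function(lat, lon) {
  s <- (lat - 5) / 40                     # 0 tropical .. 1 high latitude
  tmean <- 30 - 22 * s + 2 * sin(lon / 20)
  bio2 <- 8 + 4 * s
  bio5 <- tmean + 8 + 6 * s
  bio6 <- tmean - 8 - 14 * s
  bio7 <- bio5 - bio6
  bio12 <- 2800 * exp(-((lat - 10)^2) / 180) + 200 + 15 * cos(lon / 25)
  out <- data.frame(
    BIO1 = 10 * tmean,
    BIO2 = 10 * bio2,
    BIO3 = 100 * bio2 / bio7,
    BIO4 = 150 + 1200 * s,
    BIO5 = 10 * bio5,
    BIO6 = 10 * bio6,
    BIO7 = 10 * bio7,
    BIO8 = 10 * (tmean + 2),
    BIO9 = 10 * (tmean - 3 * s),
    BIO10 = 10 * (tmean + 3 + 2 * s),
    BIO11 = 10 * (tmean - 10 * s),
    BIO12 = bio12,
    BIO13 = 0.2 * bio12,
    BIO14 = 0.01 * bio12 + 2,
    BIO15 = 20 + 60 * s,
    BIO16 = 0.5 * bio12,
    BIO17 = 0.05 * bio12 + 5,
    BIO18 = 0.3 * bio12,
    BIO19 = 0.15 * bio12,
    npp = 0.5 + 2 * exp(-((lat - 10)^2) / 300),
    pet = 800 + 20 * tmean,
    elev = 300 + 250 * sin(lon / 10)^2 + 5 * lat)
  soil_names <- grep("^soil_", env_variables(), value = TRUE)
  for (j in seq_along(soil_names)) {
    out[[soil_names[j]]] <-
      50 + 30 * sin(lon / (5 + j) + j) * cos(lat / (7 + j))
  }
  out
}

#' Point-in-world lookups
#'
#' Vectorized lookups mapping coordinates to country, land, biome and realm
#' in a [world_default()]-style world. Ocean points return `NA`.
#'
#' @param world a `world_spec`.
#' @param lat,lon coordinate vectors (decimal degrees).
#' @return `world_country()`: country name or `NA`; `world_on_land()`:
#'   logical; `world_biome()` / `world_realm()`: label or `NA`.
#' @export
world_country <- function(world, lat, lon) {
  out <- rep(NA_character_, length(lat))
  for (i in seq_len(nrow(world$countries))) {
    co <- world$countries[i, ]
    hit <- !is.na(lat) & !is.na(lon) &
      lon >= co$lon0 & lon <= co$lon1 & lat >= co$lat0 & lat <= co$lat1
    out[hit] <- co$name
  }
  out
}

#' @rdname world_country
#' @export
world_on_land <- function(world, lat, lon) {
  !is.na(world_country(world, lat, lon))
}

#' @rdname world_country
#' @export
world_biome <- function(world, lat, lon) {
  country <- world_country(world, lat, lon)
  out <- rep(NA_character_, length(lat))
  for (i in seq_len(nrow(world$biomes))) {
    b <- world$biomes[i, ]
    hit <- !is.na(country) & country == b$country &
      lat >= b$lat0 & (lat < b$lat1 |
                         (lat == b$lat1 & b$lat1 == max(world$biomes$lat1[
                           world$biomes$country == b$country])))
    out[hit] <- b$biome
  }
  out
}

#' @rdname world_country
#' @export
world_realm <- function(world, lat, lon) {
  country <- world_country(world, lat, lon)
  world$countries$realm[match(country, world$countries$name)]
}

# Degree distance from a point to a country's rectangle (0 if inside).
country_distance <- function(world, country, lat, lon) {
  i <- match(country, world$countries$name)
  out <- rep(NA_real_, length(lat))
  ok <- !is.na(i)
  co <- world$countries[i[ok], , drop = FALSE]
  dx <- pmax(co$lon0 - lon[ok], lon[ok] - co$lon1, 0)
  dy <- pmax(co$lat0 - lat[ok], lat[ok] - co$lat1, 0)
  out[ok] <- sqrt(dx^2 + dy^2)
  out
}
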