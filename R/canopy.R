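#' Biome-to-canopy mapping schemes
#'
#' Maps each of the 14 [olson_biomes] to a canopy class. Under the
#' `primary` scheme, forest-type biomes (tropical/subtropical moist, dry
#' and coniferous forests; temperate broadleaf/mixed and conifer forests;
#' boreal forest; mangroves; Mediterranean forests, woodlands & scrub) are
#' `closed`; grasslands/savannas/shrublands, tundra and deserts are
#' `open`. The `mediterranean_open` scheme differs only in treating the
#' Mediterranean biome as open, for the robustness analysis in which those
#' mixed-canopy communities are regarded as grassland-like.
#'
#' @param name scheme name.
#' @return named character vector, biome label -> `"closed"` / `"open"`,
#'   with the scheme name as attribute `"scheme"`.
#' @export
canopy_scheme <- function(name = c("primary", "mediterranean_open")) {
  name <- match.arg(name)
  open <- c("Tropical & Subtropical Grasslands, Savannas & Shrublands",
            "Temperate Grasslands, Savannas & Shrublands",
            "Flooded Grasslands & Savannas",
            "Montane Grasslands & Shrublands",
            "Tundra",
            "Deserts & Xeric Shrublands")
  map <- setNames(ifelse(olson_biomes %in% open, "open", "closed"),
                  olson_biomes)
  if (name == "mediterranean_open") {
    map["Mediterranean Forests, Woodlands & Scrub"] <- "open"
  }
  structure(map, scheme = name)
}

#' Threshold-code the two binary canopy characters
#'
#' A species is scored as occupying closed-canopy habitat if strictly more
#' than `threshold` (default one third) of its unique records fall in
#' closed-canopy biomes, and likewise for open-canopy habitat. The
#' inequality is strict: a share of exactly one third does not set the
#' flag.
#'
#' @param biome_proportions named numeric vector of per-biome occupancy
#'   proportions for one species (must sum to 1).
#' @param scheme a [canopy_scheme()] mapping (or custom named vector with
#'   values `"closed"`/`"open"` covering every biome present).
#' @param threshold occupancy fraction above which a flag is set.
#' @return integer vector `c(closed = 0/1, open = 0/1)`.
#' @export
code_flags <- function(biome_proportions, scheme = canopy_scheme(),
                       threshold = 1 / 3) {
  stopifnot(!is.null(names(biome_proportions)))
  if (abs(sum(biome_proportions) - 1) > 1e-8) {
    stop("biome proportions must sum to 1")
  }
  unmapped <- setdiff(names(biome_proportions), names(scheme))
  if (length(unmapped) > 0) {
    stop("biomes not covered by scheme: ", paste(unmapped, collapse = ", "))
  }
  canopy <- scheme[names(biome_proportions)]
  closed_share <- sum(biome_proportions[canopy == "closed"])
  open_share <- sum(biome_proportions[canopy == "open"])
  flags <- c(closed = as.integer(closed_share > threshold),
             open = as.integer(open_share > threshold))
  if (all(flags == 0L)) {
    stop("both canopy flags are 0; shares ", closed_share, " / ", open_share,
         " cannot both fall at or below the threshold when classes partition")
  }
  flags
}

#' Composite three-state canopy character from the binary flags
#'
#' `(closed = 1, open = 0)` -> `closed`; `(1, 1)` -> `both`;
#' `(0, 1)` -> `open`. `(0, 0)` is invalid.
#'
#' @param closed_flag,open_flag binary flags from [code_flags()].
#' @return one of `"closed"`, `"both"`, `"open"`.
#' @export
composite_state <- function(closed_flag, open_flag) {
  stopifnot(closed_flag %in% 0:1, open_flag %in% 0:1)
  if (closed_flag == 1 && open_flag == 0) return("closed")
  if (closed_flag == 1 && open_flag == 1) return("both")
  if (closed_flag == 0 && open_flag == 1) return("open")
  stop("invalid flag combination (0, 0)")
}

#' Code the canopy character for every species
#'
#' @param biome_props a `species_summary` (its `$biome` table is used) or
#'   a long data frame with columns `species`, `biome`, `proportion`.
#' @param scheme a [canopy_scheme()].
#' @param threshold passed to [code_flags()].
#' @return data frame `species`, `closed_flag`, `open_flag`, `state`, with
#'   the scheme name as attribute `"scheme"`.
#' @export
code_canopy <- function(biome_props, scheme = canopy_scheme(),
                        threshold = 1 / 3) {
  if (inherits(biome_props, "species_summary")) biome_props <- biome_props$biome
  stopifnot(all(c("species", "biome", "proportion") %in% names(biome_props)))
  sp <- split(biome_props, biome_props$species)
  out <- do.call(rbind, lapply(names(sp), function(nm) {
    props <- setNames(sp[[nm]]$proportion, sp[[nm]]$biome)
    fl <- code_flags(props, scheme, threshold)
    data.frame(species = nm, closed_flag = fl[["closed"]],
               open_flag = fl[["open"]],
               state = composite_state(fl[["closed"]], fl[["open"]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "scheme") <- attr(scheme, "scheme")
  out
}
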