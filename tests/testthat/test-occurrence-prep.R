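# A tiny hand-built occurrence table targeting specific cleaning branches.
manual_records <- function() {
  world <- world_default()
  env0 <- world$climate(10, -120)
  rec <- data.frame(record_id = 1:5, species = "sp1",
                    lat = c(10, 10, 10, 11, 12),
                    lon = c(-120, -120, -120, -121, -122),
                    country = "Aridia", stringsAsFactors = FALSE)
  rec$biome <- world_biome(world, rec$lat, rec$lon)
  rec$realm <- world_realm(world, rec$lat, rec$lon)
  cbind(rec, world$climate(rec$lat, rec$lon))
}

test_that("rejection reasons distinguish unknown country, off-land and wrong country", {
  world <- world_default()
  rec <- manual_records()[1:3, ]
  rec$country[1] <- "Atlantis"            # unknown
  rec$lat[2] <- 50; rec$lon[2] <- 0       # ocean under every variant
  rec$lat[3] <- 35; rec$lon[3] <- -90     # in Steppia, far from Aridia
  val <- validate_records(rec, world)
  expect_equal(nrow(val$records), 0L)
  expect_equal(val$rejected$reason,
               c("unknown-country", "off-land", "wrong-country"))
})

test_that("repair variants are tried in the documented fixed order", {
  world <- world_default()
  rec <- manual_records()[1:3, ]
  rec$lat[2] <- -rec$lat[2]                       # needs lat_flip
  tmp <- rec$lat[3]; rec$lat[3] <- rec$lon[3]; rec$lon[3] <- tmp  # needs swap
  val <- validate_records(rec, world)
  expect_equal(val$records$repair, c("as_given", "lat_flip", "swap"))
  expect_equal(val$records$lat, c(10, 10, 10))
  expect_equal(val$records$lon, c(-120, -120, -120))
})

test_that("deduplication keeps one record per distinct coordinate, matching a set oracle", {
  rec <- manual_records()
  ded <- dedupe_unique(rec)
  expect_equal(nrow(ded), 3L)                 # 3 identical coords collapse
  expect_equal(ded$record_id[1], 1L)          # first occurrence kept
  all_distinct <- manual_records()
  all_distinct$lat <- all_distinct$lat + seq_len(5) / 10
  expect_equal(nrow(dedupe_unique(all_distinct)), 5L)

  # coordinates that collide only after repair, against brute-force sets
  world <- world_default()
  rec2 <- manual_records()
  tmp <- rec2$lat[2]; rec2$lat[2] <- rec2$lon[2]; rec2$lon[2] <- tmp
  repaired <- validate_records(rec2, world)$records
  ded2 <- dedupe_unique(repaired)
  oracle_n <- length(unique(paste(repaired$species, repaired$lat,
                                  repaired$lon)))
  expect_equal(nrow(ded2), oracle_n)
})

test_that("complete-case filtering matches a brute-force row scan", {
  rec <- manual_records()
  expect_equal(nrow(suppressMessages(filter_complete(rec))), 5L)
  rec$BIO3[2] <- NA
  rec$soil_ph[4] <- NA
  rec$npp[4] <- NA
  kept <- suppressMessages(filter_complete(rec))
  scan <- rec[apply(!is.na(rec[env_variables()]), 1, all), ]
  expect_equal(kept$record_id, scan$record_id)
  expect_equal(attr(kept, "n_dropped"), 2L)
  # only the required variables matter
  kept_sub <- suppressMessages(filter_complete(rec, required = c("BIO1", "BIO12")))
  expect_equal(nrow(kept_sub), 5L)
})

test_that("species summaries divide temperature variables by 10 and tabulate proportions", {
  rec <- manual_records()[1, ]
  rec$BIO1 <- 215
  s <- summarize_species(rec)
  expect_equal(s$climate$BIO1, 21.5)
  expect_equal(s$climate$n_records, 1L)

  rec3 <- manual_records()[1:3, ]
  rec3$lat <- c(10, 11, 12)                  # keep records distinct
  rec3$BIO12 <- c(100, 300, 200)
  rec3$BIO4 <- c(700, 800, 900)              # native scale, no division
  s3 <- summarize_species(rec3)
  expect_equal(s3$climate$BIO12, 200)
  expect_equal(s3$climate$BIO4, 800)

  rec10 <- manual_records()[rep(1, 10), ]
  rec10$record_id <- 1:10
  rec10$lat <- 10 + (1:10) / 10
  rec10$biome <- c(rep("Deserts & Xeric Shrublands", 4),
                   rep("Tropical & Subtropical Moist Broadleaf Forests", 6))
  s10 <- summarize_species(rec10)
  des <- s10$biome[s10$biome$biome == "Deserts & Xeric Shrublands", ]
  expect_equal(des$proportion, 0.4)
  expect_equal(sum(s10$biome$proportion), 1, tolerance = 1e-12)
  expect_equal(sum(s10$realm$proportion), 1, tolerance = 1e-12)
})

test_that("the cleaning pipeline is idempotent and recovers the corruption-free truth", {
  world <- world_default()
  rec <- generate_occurrences(paste0("t", 1:10), world, n_per_species = 8,
                              error_rates = list(swap = 0.3, sign_flip = 0.2),
                              seed = 31)
  p1 <- suppressMessages(prep_occurrences(rec, world))
  # second pass over already-clean records changes nothing
  p2 <- suppressMessages(prep_occurrences(p1$records, world))
  expect_equal(p2$summary$climate, p1$summary$climate)
  expect_equal(p2$summary$biome, p1$summary$biome)
  expect_equal(nrow(p2$rejected), 0L)

  # swap/flip corruption is fully repaired: summaries equal those computed
  # directly from the truth sidecar
  tr <- occurrence_truth(rec)
  truth_rec <- rec
  truth_rec$lat <- tr$true_lat
  truth_rec$lon <- tr$true_lon
  p_truth <- suppressMessages(prep_occurrences(truth_rec, world))
  expect_equal(p1$summary$climate, p_truth$summary$climate)
})

test_that("species with zero surviving records are reported as omitted", {
  world <- world_default()
  rec <- generate_occurrences(c("t1", "t2"), world, n_per_species = 3,
                              seed = 33)
  rec <- rec[rec$species != "t2", ]
  expect_message(summarize_species(rec, species = c("t1", "t2")),
                 "t2")
})
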