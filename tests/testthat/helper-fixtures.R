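# Hand-built fixtures for unit tests. Scores and caseloads are duplicated
# across the two service areas unless a test overrides them.

suppressPackageStartupMessages(library(dplyr))

mk_fac <- function(id, authority = "public", level = "first_level",
                   district = "d1", lon = 0, lat = 0, caseload = 100,
                   structural = 0.5, process = 0.5, skilled = TRUE) {
  tibble::tibble(
    facility_id = id, authority = authority, level = level,
    district = district, lon = lon, lat = lat,
    caseload_sick_child = caseload, caseload_delivery = caseload,
    structural_sick_child = structural, structural_delivery = structural,
    process_sick_child = process, process_delivery = process,
    skilled = skilled
  )
}

mk_cluster <- function(id, lon = 0, lat = 0, district = "d1", weight = 1) {
  tibble::tibble(cluster_id = id, lon = lon, lat = lat, district = district,
                 weight = weight)
}

mk_ep <- function(id, cluster = "C1", area = "delivery",
                  category = "public:first_level", stated = NA_character_,
                  weight = 1) {
  tibble::tibble(episode_id = id, cluster_id = cluster, service_area = area,
                 weight = weight, source_category = category,
                 stated_facility_id = stated)
}

mk_region <- function(facilities, clusters, episodes, metadata = list()) {
  region_dataset(facilities, clusters, episodes, metadata)
}

# Small generator config so property tests stay fast.
tiny_config <- function(seed = 1, ...) {
  generator_config(
    n_clusters = 8, n_deliveries = 40, n_sick_children = 30,
    facility_counts = c("public:first_level" = 18L,
                        "private:first_level" = 5L,
                        "religious:first_level" = 4L,
                        "public:referral" = 2L,
                        "private:referral" = 1L),
    n_districts = 3, n_towns = 4, region_extent_km = 100,
    seed = seed, ...
  )
}

# Independent haversine used as the distance/nearest-scan oracle; written
# from the closed form, not via the package or geosphere.
oracle_hav <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371.0088 * asin(pmin(1, sqrt(a)))
}
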