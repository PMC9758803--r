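# Region data model: a facility census, household-survey clusters, and care
# episodes, held as three tibbles inside a light S3 container. The column
# dictionary is fixed (see below); unknown extra columns are preserved but
# ignored by the pipeline.
#
# facilities: facility_id, authority, level, district, lon, lat,
#   caseload_sick_child, caseload_delivery, structural_sick_child,
#   structural_delivery, process_sick_child, process_delivery, skilled
# clusters:   cluster_id, lon, lat, district, weight
# episodes:   episode_id, cluster_id, service_area, weight, source_category,
#   stated_facility_id  (one row per reported source; a "none" row means no
#   care was sought; sick-child episodes may have several source rows)

facility_columns <- function() {
  c("facility_id", "authority", "level", "district", "lon", "lat",
    "caseload_sick_child", "caseload_delivery",
    "structural_sick_child", "structural_delivery",
    "process_sick_child", "process_delivery", "skilled")
}

cluster_columns <- function() c("cluster_id", "lon", "lat", "district", "weight")

episode_columns <- function() {
  c("episode_id", "cluster_id", "service_area", "weight",
    "source_category", "stated_facility_id")
}

facility_score_columns <- function() {
  c("structural_sick_child", "structural_delivery",
    "process_sick_child", "process_delivery")
}

check_schema <- function(tbl, required, what) {
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(tbl)
}

#' Assemble a region dataset
#'
#' Bundles a facility census, household clusters, and care episodes into a
#' validated `region` object. Stated facility ids in the episode table that
#' do not resolve to a facility are retained and flagged in the derived
#' `unresolvable` column (they take the category-average fallback under
#' exact-match linking), mirroring survey respondents whose reported source
#' of care was not covered by the provider assessment.
#'
#' @param facilities,clusters,episodes Data frames following the column
#'   dictionary documented in [read_region()].
#' @param metadata Free-form list (generator config, seed, extent, ...).
#' @return An object of class `region`: a list with elements `facilities`,
#'   `clusters`, `episodes` (tibbles) and `metadata`.
#' @export
region_dataset <- function(facilities, clusters, episodes, metadata = list()) {
  facilities <- as_tibble(facilities)
  clusters <- as_tibble(clusters)
  episodes <- as_tibble(episodes)

  check_schema(facilities, facility_columns(), "facility")
  check_schema(clusters, cluster_columns(), "cluster")
  check_schema(episodes, episode_columns(), "episode")

  for (col in c("facility_id", "district")) {
    facilities[[col]] <- as.character(facilities[[col]])
  }
  for (col in c("cluster_id", "district")) {
    clusters[[col]] <- as.character(clusters[[col]])
  }
  for (col in c("episode_id", "cluster_id", "source_category",
                "stated_facility_id")) {
    episodes[[col]] <- as.character(episodes[[col]])
  }

  dup <- facilities$facility_id[duplicated(facilities$facility_id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate facility_id: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  for (col in facility_score_columns()) {
    s <- facilities[[col]]
    bad <- which(!is.na(s) & (s < 0 | s > 1))
    if (length(bad) > 0) {
      stop(sprintf("facility %s: %s = %g outside [0, 1]",
                   facilities$facility_id[bad[1]], col, s[bad[1]]),
           call. = FALSE)
    }
  }

  episodes$unresolvable <- !is.na(episodes$stated_facility_id) &
    !(episodes$stated_facility_id %in% facilities$facility_id)

  structure(
    list(facilities = facilities, clusters = clusters, episodes = episodes,
         metadata = metadata),
    class = "region"
  )
}

#' Read a region from delimited-text tables
#'
#' Reads the facility, cluster, and episode tables (comma-separated, UTF-8,
#' header row) and returns a validated [region_dataset()]. The column
#' dictionary is:
#'
#' * facilities: `facility_id`, `authority` (public|private|religious|ngo),
#'   `level` (first_level|referral), `district`, `lon`, `lat` (WGS84 decimal
#'   degrees), `caseload_sick_child`, `caseload_delivery` (annual volumes),
#'   `structural_sick_child`, `structural_delivery`, `process_sick_child`,
#'   `process_delivery` (scores in \[0, 1\]), `skilled` (logical).
#' * clusters: `cluster_id`, `lon`, `lat` (centroid), `district`, `weight`.
#' * episodes: `episode_id`, `cluster_id`, `service_area`
#'   (sick_child|delivery), `weight`, `source_category` (a provider category
#'   such as `public:first_level`, or `unskilled`, or `none`),
#'   `stated_facility_id` (optional).
#'
#' Unknown extra columns are preserved but ignored. Episodes whose stated
#' facility id is absent from the facility table are loaded and flagged
#' `unresolvable`, not dropped.
#'
#' @param facility_path,cluster_path,episode_path Paths to the three CSVs.
#' @return A `region` object.
#' @export
read_region <- function(facility_path, cluster_path, episode_path) {
  for (p in c(facility_path, cluster_path, episode_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  facilities <- readr::read_csv(facility_path, show_col_types = FALSE,
                                progress = FALSE)
  clusters <- readr::read_csv(cluster_path, show_col_types = FALSE,
                              progress = FALSE)
  episodes <- readr::read_csv(episode_path, show_col_types = FALSE,
                              progress = FALSE)
  if (!"stated_facility_id" %in% names(episodes)) {
    stop("episode table is missing required column(s): stated_facility_id",
         call. = FALSE)
  }
  episodes$stated_facility_id <- as.character(episodes$stated_facility_id)
  region_dataset(facilities, clusters, episodes,
                 metadata = list(source = list(facilities = facility_path,
                                               clusters = cluster_path,
                                               episodes = episode_path)))
}

#' Write a region to delimited-text tables plus a GeoJSON point layer
#'
#' Writes `facilities.csv`, `clusters.csv`, `episodes.csv` and
#' `points.geojson` (RFC 7946 FeatureCollection of facility and cluster
#' points) into `directory`. Numeric columns are written at full round-trip
#' precision so that `read_region()` reproduces the region exactly.
#'
#' @param region A `region` object with at least one facility.
#' @param directory Output directory (created if needed).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_region <- function(region, directory) {
  stopifnot(inherits(region, "region"))
  if (nrow(region$facilities) == 0) {
    stop("a region must contain at least one facility", call. = FALSE)
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop(sprintf("cannot create directory: %s", directory), call. = FALSE)
  }
  paths <- c(
    facilities = file.path(directory, "facilities.csv"),
    clusters = file.path(directory, "clusters.csv"),
    episodes = file.path(directory, "episodes.csv"),
    geojson = file.path(directory, "points.geojson")
  )
  readr::write_csv(region$facilities, paths[["facilities"]], progress = FALSE)
  readr::write_csv(region$clusters, paths[["clusters"]], progress = FALSE)
  episodes <- region$episodes
  episodes$unresolvable <- NULL # derived; recomputed on read
  readr::write_csv(episodes, paths[["episodes"]], progress = FALSE)

  point_feature <- function(id, type, lon, lat, extra = list()) {
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(lon, lat)),
         properties = c(list(id = id, feature_type = type), extra))
  }
  f <- region$facilities
  cl <- region$clusters
  features <- c(
    lapply(seq_len(nrow(f)), function(i) {
      point_feature(f$facility_id[i], "facility", f$lon[i], f$lat[i],
                    list(category = make_category(f$authority[i], f$level[i]),
                         district = f$district[i]))
    }),
    lapply(seq_len(nrow(cl)), function(i) {
      point_feature(cl$cluster_id[i], "cluster", cl$lon[i], cl$lat[i],
                    list(district = cl$district[i]))
    })
  )
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, paths[["geojson"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Validate a region against the data-model invariants
#'
#' Returns findings rather than raising errors: an empty character vector for
#' a valid region, otherwise one message per violated invariant, each
#' locating the offending record. Checked invariants include score and
#' caseload bounds, positive weights, coordinate ranges, resolvable episode
#' cluster ids, single-source delivery episodes, and consistency of "none"
#' (no care sought) rows.
#'
#' @param region A `region` object.
#' @return Character vector of findings (empty when valid).
#' @export
validate_region <- function(region) {
  stopifnot(inherits(region, "region"))
  f <- region$facilities
  cl <- region$clusters
  ep <- region$episodes
  findings <- character(0)
  add <- function(msgs) findings <<- c(findings, msgs)

  for (col in facility_score_columns()) {
    bad <- which(is.na(f[[col]]) | f[[col]] < 0 | f[[col]] > 1)
    if (length(bad) > 0) {
      add(sprintf("facility %s: %s outside [0, 1]", f$facility_id[bad], col))
    }
  }
  for (area in service_areas()) {
    col <- caseload_col(area)
    bad <- which(is.na(f[[col]]) | f[[col]] < 0)
    if (length(bad) > 0) {
      add(sprintf("facility %s: negative caseload (%s)",
                  f$facility_id[bad], col))
    }
  }
  bad <- which(!(f$authority %in% region_authorities()) |
                 !(f$level %in% region_levels()))
  if (length(bad) > 0) {
    add(sprintf("facility %s: unknown authority/level", f$facility_id[bad]))
  }
  bad <- which(abs(f$lat) > 90 | abs(f$lon) > 180)
  if (length(bad) > 0) {
    add(sprintf("facility %s: coordinates out of range", f$facility_id[bad]))
  }

  dup <- unique(cl$cluster_id[duplicated(cl$cluster_id)])
  if (length(dup) > 0) add(sprintf("duplicate cluster_id %s", dup))
  bad <- which(is.na(cl$weight) | cl$weight <= 0)
  if (length(bad) > 0) {
    add(sprintf("cluster %s: non-positive weight", cl$cluster_id[bad]))
  }
  bad <- which(abs(cl$lat) > 90 | abs(cl$lon) > 180)
  if (length(bad) > 0) {
    add(sprintf("cluster %s: coordinates out of range", cl$cluster_id[bad]))
  }
  extent <- region$metadata$extent
  if (!is.null(extent)) {
    bad <- which(cl$lon < extent$lon[1] | cl$lon > extent$lon[2] |
                   cl$lat < extent$lat[1] | cl$lat > extent$lat[2])
    if (length(bad) > 0) {
      add(sprintf("cluster %s: centroid outside region extent",
                  cl$cluster_id[bad]))
    }
  }

  bad <- which(!(ep$cluster_id %in% cl$cluster_id))
  if (length(bad) > 0) {
    add(sprintf("episode %s: unknown cluster_id %s",
                ep$episode_id[bad], ep$cluster_id[bad]))
  }
  bad <- which(!(ep$service_area %in% service_areas()))
  if (length(bad) > 0) {
    add(sprintf("episode %s: unknown service_area", ep$episode_id[bad]))
  }
  bad <- which(!(ep$source_category %in% source_categories()))
  if (length(bad) > 0) {
    add(sprintf("episode %s: unknown source_category '%s'",
                ep$episode_id[bad], ep$source_category[bad]))
  }
  bad <- which(is.na(ep$weight) | ep$weight <= 0)
  if (length(bad) > 0) {
    add(sprintf("episode %s: non-positive weight", ep$episode_id[bad]))
  }

  per_ep <- ep %>%
    group_by(.data$episode_id) %>%
    summarise(
      n_rows = n(),
      n_none = sum(.data$source_category == "none"),
      area = .data$service_area[1],
      n_area = n_distinct(.data$service_area),
      n_cluster = n_distinct(.data$cluster_id),
      .groups = "drop"
    )
  bad <- per_ep$episode_id[per_ep$area == "delivery" & per_ep$n_rows > 1]
  if (length(bad) > 0) {
    add(sprintf("episode %s: delivery episode has >1 source", bad))
  }
  bad <- per_ep$episode_id[per_ep$n_none > 0 & per_ep$n_rows > per_ep$n_none]
  if (length(bad) > 0) {
    add(sprintf("episode %s: 'none' row combined with other sources", bad))
  }
  bad <- per_ep$episode_id[per_ep$n_area > 1 | per_ep$n_cluster > 1]
  if (length(bad) > 0) {
    add(sprintf("episode %s: inconsistent service_area/cluster across rows",
                bad))
  }

  findings
}

#' @export
print.region <- function(x, ...) {
  n_ep <- dplyr::n_distinct(x$episodes$episode_id)
  cat(sprintf(
    "<region> %d facilities, %d clusters, %d episodes (%d source rows)\n",
    nrow(x$facilities), nrow(x$clusters), n_ep, nrow(x$episodes)))
  counts <- table(make_category(x$facilities$authority, x$facilities$level))
  cat("  facilities:",
      paste(sprintf("%s=%d", names(counts), as.integer(counts)),
            collapse = ", "), "\n")
  ep <- dplyr::distinct(x$episodes, .data$episode_id, .data$service_area)
  areas <- table(ep$service_area)
  cat("  episodes:  ",
      paste(sprintf("%s=%d", names(areas), as.integer(areas)),
            collapse = ", "), "\n")
  invisible(x)
}
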