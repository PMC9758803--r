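# Linking methods: assigning each care episode the structural and process
# quality scores of its (actual or putative) source of care.
#
# * exact:     the specific stated facility; always evaluated against the
#              full census (the exact-match reference is computed once from
#              the complete provider assessment, never from a sample).
# * euclidean: the closest facility, as the crow flies, within the reported
#              provider category.
# * admin:     the caseload-weighted mean score of all facilities of the
#              reported category in the episode's district.
#
# Whenever a skilled source cannot be matched (unresolvable stated id, or no
# facility of the category in the relevant set), the episode receives the
# category-average fallback score. Unskilled sources (pharmacies, community
# health workers) never link: an episode with only unskilled sources counts
# as receiving no skilled care.

earth_radius_km <- 6371.0088

#' Great-circle distance in kilometres
#'
#' Haversine distance on the WGS84 sphere with mean Earth radius
#' 6371.0088 km. Vectorised over coordinate pairs.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distance(s) in kilometres.
#' @export
distance_km <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop("longitude outside [-180, 180]", call. = FALSE)
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = earth_radius_km)
}

# Full cross-distance matrix (rows = first point set, cols = second).
dist_matrix_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distm(cbind(lon1, lat1), cbind(lon2, lat2),
                   fun = function(p1, p2) {
                     geosphere::distHaversine(p1, p2, r = earth_radius_km)
                   })
}

fac_category <- function(facilities) {
  make_category(facilities$authority, facilities$level)
}

# Weighted mean that degrades to the unweighted mean when total weight is 0.
caseload_mean <- function(x, w) {
  if (length(x) == 0) return(NA_real_)
  if (sum(w) > 0) weighted.mean(x, w) else mean(x)
}

#' Category-average fallback score
#'
#' The caseload-weighted mean structural and process score over all skilled
#' facilities of `category` in `facilities`. If the category is entirely
#' absent from that set (e.g. after sampling), the census-wide category mean
#' is used instead and flagged via `from_census`. Used for episodes whose
#' reported source of care cannot be matched to a specific facility.
#'
#' @param category Provider category string, e.g. `"public:first_level"`.
#' @param facilities Facility set in effect (census or sample).
#' @param service_area `"sick_child"` or `"delivery"`.
#' @param census Full census, consulted when the category is missing from
#'   `facilities`. Defaults to `facilities`.
#' @param weighted Weight by service-area caseload (default) or not.
#' @return List with `structural`, `process`, `from_census`.
#' @export
fallback_score <- function(category, facilities, service_area,
                           census = NULL, weighted = TRUE) {
  pick <- function(tbl) {
    tbl[tbl$skilled & fac_category(tbl) == category, , drop = FALSE]
  }
  fac <- pick(facilities)
  from_census <- FALSE
  if (nrow(fac) == 0 && !is.null(census)) {
    fac <- pick(census)
    from_census <- TRUE
  }
  if (nrow(fac) == 0) {
    stop(sprintf("no facility of category '%s' in facility set or census",
                 category), call. = FALSE)
  }
  w <- if (weighted) fac[[caseload_col(service_area)]] else rep(1, nrow(fac))
  list(
    structural = caseload_mean(fac[[score_col("structural", service_area)]], w),
    process = caseload_mean(fac[[score_col("process", service_area)]], w),
    from_census = from_census
  )
}

#' Average scores across multiple skilled sources
#'
#' A sick child may have sought care from several providers over one illness
#' episode; such episodes receive the unweighted mean of the scores of the
#' skilled sources they used (unskilled sources are excluded before calling
#' this).
#'
#' @param scores Data frame with columns `structural` and `process`, one row
#'   per skilled source.
#' @return List with mean `structural` and `process`.
#' @export
combine_multi_source <- function(scores) {
  if (is.null(nrow(scores)) || nrow(scores) == 0) {
    stop("combine_multi_source() needs at least one skilled source score",
         call. = FALSE)
  }
  list(structural = mean(scores$structural), process = mean(scores$process))
}

# Per-source score assignment for one linking method. Returns one row per
# skilled source: episode_id, structural, process, facility_id (NA when the
# fallback was used), fallback.
link_sources <- function(src, method, facset, census, service_area, clusters) {
  s_col <- score_col("structural", service_area)
  p_col <- score_col("process", service_area)

  if (nrow(src) == 0) {
    return(tibble(episode_id = character(0), structural = double(0),
                  process = double(0), facility_id = character(0),
                  fallback = logical(0)))
  }

  if (method == "exact") {
    fac_scores <- tibble(
      stated_facility_id = census$facility_id,
      facility_id = census$facility_id,
      structural = census[[s_col]],
      process = census[[p_col]]
    )
    out <- src %>%
      select("episode_id", "source_category", "stated_facility_id") %>%
      left_join(fac_scores, by = "stated_facility_id")
    fb_set <- census
  } else if (method == "euclidean") {
    cl <- clusters %>% select("cluster_id", cl_lon = "lon", cl_lat = "lat")
    src_cl <- src %>%
      select("episode_id", "source_category", "cluster_id") %>%
      left_join(cl, by = "cluster_id")
    cats <- unique(src_cl$source_category)
    nearest <- purrr::map_dfr(cats, function(cat) {
      fc <- facset[facset$skilled & fac_category(facset) == cat, , drop = FALSE]
      if (nrow(fc) == 0) return(NULL)
      d <- dist_matrix_km(clusters$lon, clusters$lat, fc$lon, fc$lat)
      idx <- max.col(-d, ties.method = "first") # fc sorted by id: ties -> smallest
      tibble(cluster_id = clusters$cluster_id,
             source_category = cat,
             facility_id = fc$facility_id[idx],
             structural = fc[[s_col]][idx],
             process = fc[[p_col]][idx])
    })
    if (nrow(nearest) == 0) {
      nearest <- tibble(cluster_id = character(0),
                        source_category = character(0),
                        facility_id = character(0),
                        structural = double(0), process = double(0))
    }
    out <- src_cl %>%
      left_join(nearest, by = c("cluster_id", "source_category")) %>%
      select("episode_id", "source_category", "facility_id",
             "structural", "process")
    fb_set <- facset
  } else { # admin
    agg <- facset %>%
      filter(.data$skilled) %>%
      mutate(source_category = fac_category(.)) %>%
      group_by(.data$district, .data$source_category) %>%
      summarise(
        structural = caseload_mean(.data[[s_col]],
                                   .data[[caseload_col(service_area)]]),
        process = caseload_mean(.data[[p_col]],
                                .data[[caseload_col(service_area)]]),
        facility_id = paste(sort(.data$facility_id), collapse = ";"),
        .groups = "drop"
      )
    cl <- clusters %>% select("cluster_id", "district")
    out <- src %>%
      select("episode_id", "source_category", "cluster_id") %>%
      left_join(cl, by = "cluster_id") %>%
      left_join(agg, by = c("district", "source_category")) %>%
      select("episode_id", "source_category", "facility_id",
             "structural", "process")
    fb_set <- facset
  }

  out$fallback <- is.na(out$structural)
  fb_cats <- unique(out$source_category[out$fallback])
  for (cat in fb_cats) {
    fb <- fallback_score(cat, fb_set, service_area, census = census)
    rows <- out$fallback & out$source_category == cat
    out$structural[rows] <- fb$structural
    out$process[rows] <- fb$process
    out$facility_id[rows] <- NA_character_
  }
  out %>% select("episode_id", "structural", "process", "facility_id",
                 "fallback")
}

#' Link care episodes to provider quality scores
#'
#' Applies one linking method to every episode of a service area and returns
#' one result row per episode. Exact-match linking always evaluates against
#' the region's full census; the ecological methods (`euclidean`, `admin`)
#' use `facilities` (a sampled facility set, or the census by default).
#' Skilled sources that cannot be matched receive the category fallback via
#' [fallback_score()]; multi-source episodes are averaged via
#' [combine_multi_source()]; episodes with no skilled source get
#' `skilled_care = FALSE` and missing scores (they contribute zero to
#' adjusted coverage).
#'
#' @param region A `region` object.
#' @param method `"exact"`, `"euclidean"` or `"admin"`.
#' @param service_area `"sick_child"` or `"delivery"`.
#' @param facilities Facility set for the ecological methods; defaults to the
#'   census (`region$facilities`).
#' @return Tibble with one row per episode: `episode_id`, `method`,
#'   `service_area`, `structural`, `process`, `linked_facilities`
#'   (semicolon-joined ids, empty when only fallbacks were used),
#'   `fallback_used`, `skilled_care`.
#' @export
link_episodes <- function(region, method = c("exact", "euclidean", "admin"),
                          service_area = c("sick_child", "delivery"),
                          facilities = NULL) {
  stopifnot(inherits(region, "region"))
  method <- match.arg(method)
  service_area <- match.arg(service_area)

  census <- region$facilities %>%
    filter(.data$skilled) %>%
    arrange(.data$facility_id)
  facset <- if (is.null(facilities) || method == "exact") {
    census
  } else {
    as_tibble(facilities) %>%
      filter(.data$skilled) %>%
      arrange(.data$facility_id)
  }

  eps <- region$episodes %>% filter(.data$service_area == !!service_area)
  ep_info <- eps %>% distinct(.data$episode_id)
  src_skilled <- eps %>%
    filter(!(.data$source_category %in% c("none", "unskilled")))

  per_src <- link_sources(src_skilled, method, facset, census, service_area,
                          region$clusters)
  per_ep <- per_src %>%
    group_by(.data$episode_id) %>%
    summarise(
      structural = mean(.data$structural),
      process = mean(.data$process),
      fallback_used = any(.data$fallback),
      linked_facilities = paste(
        sort(unique(.data$facility_id[!is.na(.data$facility_id)])),
        collapse = ";"),
      .groups = "drop"
    )

  ep_info %>%
    left_join(per_ep, by = "episode_id") %>%
    mutate(
      skilled_care = .data$episode_id %in% src_skilled$episode_id,
      fallback_used = ifelse(is.na(.data$fallback_used), FALSE,
                             .data$fallback_used),
      linked_facilities = ifelse(is.na(.data$linked_facilities), "",
                                 .data$linked_facilities),
      method = method,
      service_area = !!service_area
    ) %>%
    arrange(.data$episode_id) %>%
    select("episode_id", "method", "service_area", "structural", "process",
           "linked_facilities", "fallback_used", "skilled_care")
}
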