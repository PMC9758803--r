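# Synthetic region generator. Emulates the statistical structure the
# analysis assumes: a household survey of clusters with care episodes
# (delivery and sick child), a facility census dominated by public
# first-level facilities with a handful of referral facilities, bounded
# unimodal quality-score spreads within provider categories, gravity-style
# provider choice (caseload x distance decay, optionally tilted towards
# higher process quality), and a configurable fraction of care-seekers whose
# stated source of care cannot be matched to the assessment.

# Region anchor: a rural west-African setting; the extent square is mapped to
# WGS84 degrees around this point with a locally-affine approximation.
region_anchor <- function() c(lon = -5.62, lat = 9.45)

km_per_deg_lat <- 110.574
km_per_deg_lon <- function(lat) 111.320 * cos(lat * pi / 180)

default_category_mix <- function() {
  list(
    delivery = c("public:first_level" = 0.460,
                 "public:referral" = 0.120,
                 "private:first_level" = 0.050,
                 "religious:first_level" = 0.022,
                 "none" = 0.348),
    sick_child = c("public:first_level" = 0.270,
                   "public:referral" = 0.030,
                   "private:first_level" = 0.030,
                   "religious:first_level" = 0.020,
                   "unskilled" = 0.082,
                   "none" = 0.568)
  )
}

default_quality_params <- function() {
  base <- tibble(
    category = c("public:first_level", "private:first_level",
                 "religious:first_level", "ngo:first_level",
                 "public:referral", "private:referral"),
    structural_mean = c(0.55, 0.62, 0.60, 0.60, 0.82, 0.80),
    structural_sd = c(0.07, 0.08, 0.08, 0.08, 0.05, 0.05),
    process_mean = c(0.50, 0.56, 0.54, 0.55, 0.75, 0.72),
    process_sd = c(0.07, 0.08, 0.08, 0.08, 0.05, 0.05)
  )
  bind_rows(
    base %>% mutate(service_area = "sick_child"),
    base %>% mutate(service_area = "delivery")
  )
}

#' Configuration of the synthetic region generator
#'
#' Defaults reproduce the study conditions the pipeline is designed around:
#' 44 household clusters, 392 delivery and 183 sick-child episodes, a census
#' of 144 public first-level, 43 private/religious first-level and 7 referral
#' facilities (5 public, 2 private), a delivery source mix totalling 65.2%
#' facility delivery (46.0% public first-level), a sick-child mix totalling
#' 43.2% care sought (27.0% public first-level, 8.2% pharmacy/unskilled), and
#' 7% of care-seekers unlinkable to their stated source.
#'
#' @param n_clusters,n_deliveries,n_sick_children Survey dimensions.
#' @param facility_counts Named integer vector: facilities per provider
#'   category.
#' @param region_extent_km Side of the square region.
#' @param n_districts Districts (Voronoi cells around random centers; every
#'   facility and cluster belongs to exactly one).
#' @param n_towns Town centers around which facilities cluster, so that
#'   nearest-facility linking is nontrivial (some episodes bypass their
#'   nearest provider).
#' @param category_mix Per service area, a probability vector over source
#'   categories including `"unskilled"` and `"none"`; each must sum to 1.
#' @param quality_params Tibble of Beta(mean, sd) score parameters per
#'   category, service area and indicator (see `default_quality_params`).
#' @param distance_decay_km Gravity scale of provider choice: attraction
#'   decays as exp(-d / distance_decay_km).
#' @param quality_preference Tilt of provider choice towards higher process
#'   scores, as exp(quality_preference * process score); 0 makes choice
#'   independent of quality.
#' @param caseload_quality_correlation Rank correlation between caseload and
#'   process score within a service area (emulates volume-quality linkage).
#' @param care_seeking_icc Intra-cluster correlation of care-seeking: each
#'   cluster draws its own care-seeking propensity from a Beta distribution
#'   with mean equal to the configured total care-seeking probability and
#'   correlation parameter `care_seeking_icc` (0 = identical clusters). This
#'   reproduces the large design effects typical of regional cluster surveys;
#'   the marginal source mix is preserved exactly in expectation.
#' @param p_second_source Probability that a care-seeking sick-child episode
#'   reports a second source (deliveries always have a single source).
#' @param unlinkable_fraction Expected fraction of care-seeking episodes
#'   whose stated facility id is cleared (they take the fallback path under
#'   exact-match linking).
#' @param caseload_meanlog,caseload_sdlog Log-normal caseload parameters.
#' @param weight Survey weight given to every cluster and episode.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_clusters = 44L,
                             n_deliveries = 392L,
                             n_sick_children = 183L,
                             facility_counts = c("public:first_level" = 144L,
                                                 "private:first_level" = 22L,
                                                 "religious:first_level" = 21L,
                                                 "public:referral" = 5L,
                                                 "private:referral" = 2L),
                             region_extent_km = 150,
                             n_districts = 6L,
                             n_towns = 10L,
                             category_mix = default_category_mix(),
                             quality_params = default_quality_params(),
                             distance_decay_km = 25,
                             quality_preference = 0,
                             caseload_quality_correlation = 0,
                             care_seeking_icc = 0.3,
                             p_second_source = 0.10,
                             unlinkable_fraction = 0.07,
                             caseload_meanlog = log(150),
                             caseload_sdlog = 0.8,
                             weight = 1,
                             seed = 1L) {
  stopifnot(n_clusters >= 1, n_deliveries >= 1, n_sick_children >= 1,
            region_extent_km > 0, n_districts >= 1, n_towns >= 1,
            distance_decay_km > 0, quality_preference >= 0,
            caseload_quality_correlation >= 0,
            caseload_quality_correlation <= 1,
            care_seeking_icc >= 0, care_seeking_icc < 1,
            p_second_source >= 0, p_second_source <= 1,
            unlinkable_fraction >= 0, unlinkable_fraction < 1,
            weight > 0)
  if (!all(names(facility_counts) %in% facility_categories()) ||
      any(facility_counts < 0)) {
    stop("facility_counts must map provider categories to counts >= 0",
         call. = FALSE)
  }
  for (area in names(category_mix)) {
    mix <- category_mix[[area]]
    if (any(mix < 0 | mix > 1)) {
      stop(sprintf("category_mix[%s]: probabilities must lie in [0, 1]",
                   area), call. = FALSE)
    }
    if (abs(sum(mix) - 1) > 1e-9) {
      stop(sprintf("category_mix[%s] must sum to 1 (got %.12f)",
                   area, sum(mix)), call. = FALSE)
    }
    bad <- setdiff(names(mix), source_categories())
    if (length(bad) > 0) {
      stop(sprintf("category_mix[%s]: unknown category '%s'", area, bad[1]),
           call. = FALSE)
    }
    fac_cats <- intersect(names(mix)[mix > 0], facility_categories())
    absent <- fac_cats[!(fac_cats %in%
                           names(facility_counts)[facility_counts > 0])]
    if (length(absent) > 0) {
      stop(sprintf("category '%s' has positive mix probability but no facility",
                   absent[1]), call. = FALSE)
    }
  }
  if (any(quality_params$structural_mean < 0 | quality_params$structural_mean > 1 |
            quality_params$process_mean < 0 | quality_params$process_mean > 1 |
            quality_params$structural_sd < 0 | quality_params$process_sd < 0)) {
    stop("quality_params: means must lie in [0, 1] and sds must be >= 0",
         call. = FALSE)
  }
  structure(
    list(n_clusters = as.integer(n_clusters),
         n_deliveries = as.integer(n_deliveries),
         n_sick_children = as.integer(n_sick_children),
         facility_counts = facility_counts,
         region_extent_km = region_extent_km,
         n_districts = as.integer(n_districts),
         n_towns = as.integer(n_towns),
         category_mix = category_mix,
         quality_params = quality_params,
         distance_decay_km = distance_decay_km,
         quality_preference = quality_preference,
         caseload_quality_correlation = caseload_quality_correlation,
         care_seeking_icc = care_seeking_icc,
         p_second_source = p_second_source,
         unlinkable_fraction = unlinkable_fraction,
         caseload_meanlog = caseload_meanlog,
         caseload_sdlog = caseload_sdlog,
         weight = weight,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Beta draw reparameterised by (mean, sd); sd = 0 gives the mean exactly; an
# sd at or beyond the Bernoulli bound sqrt(m(1-m)) is shrunk just inside it.
rbeta_ms <- function(n, mean, sd) {
  if (sd <= 0 || mean <= 0 || mean >= 1) return(rep(mean, n))
  vmax <- mean * (1 - mean)
  v <- min(sd^2, 0.95 * vmax)
  k <- vmax / v - 1
  rbeta(n, mean * k, (1 - mean) * k)
}

#' Draw source categories for episodes
#'
#' Multinomial draw from a service area's source mix. `"none"` yields an
#' episode with no care sought; `"unskilled"` a pharmacy/CHW source with no
#' facility id.
#'
#' @param service_area Area label (recorded, not used in the draw).
#' @param mix Named probability vector summing to 1.
#' @param n Number of draws.
#' @return Character vector of category names.
#' @export
sample_source_category <- function(service_area, mix, n = 1) {
  if (abs(sum(mix) - 1) > 1e-9) {
    stop("category mix must sum to 1", call. = FALSE)
  }
  names(mix)[sample.int(length(mix), n, replace = TRUE, prob = mix)]
}

# Gravity weights of the facilities `fc` for a cluster at (lon, lat).
gravity_weights <- function(fc, lon, lat, service_area, distance_decay_km,
                            quality_preference) {
  d <- distance_km(lon, lat, fc$lon, fc$lat)
  w <- fc[[caseload_col(service_area)]] *
    exp(-d / distance_decay_km) *
    exp(quality_preference * fc[[score_col("process", service_area)]])
  if (all(w <= 0) || !all(is.finite(w))) w <- rep(1, nrow(fc))
  w
}

#' Draw a specific provider for one episode
#'
#' Chooses a facility of the requested category with probability proportional
#' to caseload x exp(-d / distance_decay_km) x exp(quality_preference x
#' process score), where d is the great-circle distance from the episode's
#' cluster centroid. With `quality_preference = 0` the choice is independent
#' of quality.
#'
#' @param cluster One-row tibble (or list) with `lon`, `lat`.
#' @param category Provider category.
#' @param facilities Facility tibble to choose from.
#' @param service_area `"sick_child"` or `"delivery"`.
#' @param distance_decay_km,quality_preference Gravity parameters.
#' @param n Number of draws.
#' @return Character vector of facility ids.
#' @export
sample_specific_provider <- function(cluster, category, facilities,
                                     service_area,
                                     distance_decay_km = 25,
                                     quality_preference = 0, n = 1) {
  fc <- facilities[facilities$skilled &
                     fac_category(facilities) == category, , drop = FALSE]
  if (nrow(fc) == 0) {
    stop(sprintf("no facility of category '%s' to draw from", category),
         call. = FALSE)
  }
  w <- gravity_weights(fc, cluster$lon, cluster$lat, service_area,
                       distance_decay_km, quality_preference)
  fc$facility_id[sample.int(nrow(fc), n, replace = TRUE, prob = w)]
}

#' Clear stated facility ids for a fraction of care-seeking episodes
#'
#' Emulates respondents who could not recall their specific source of care,
#' or whose source was not covered by the provider assessment: the stated
#' facility id is cleared (the reported category is kept) for the given
#' expected fraction of episodes carrying a stated id, independently at
#' random under the current RNG state. Affected episodes take the fallback
#' path under exact-match linking.
#'
#' @param region A `region` object.
#' @param fraction Expected masked fraction, in \[0, 1).
#' @return The region with masked episode rows and refreshed `unresolvable`
#'   flags.
#' @export
apply_unlinkable_mask <- function(region, fraction) {
  stopifnot(inherits(region, "region"), fraction >= 0, fraction < 1)
  if (fraction == 0) return(region)
  ep <- region$episodes
  with_id <- unique(ep$episode_id[!is.na(ep$stated_facility_id)])
  masked <- with_id[runif(length(with_id)) < fraction]
  ep$stated_facility_id[ep$episode_id %in% masked] <- NA_character_
  ep$unresolvable <- !is.na(ep$stated_facility_id) &
    !(ep$stated_facility_id %in% region$facilities$facility_id)
  region$episodes <- ep
  region
}

#' Generate a synthetic region
#'
#' Deterministic given the config (which includes the seed): facility and
#' episode counts match the config exactly, empirical source mixes converge
#' to the configured probabilities as episode counts grow, clusters are
#' placed uniformly in the extent, facilities cluster mildly around town
#' centers, and districts partition the region (Voronoi cells around random
#' centers). Quality scores are Beta(mean, sd) draws per provider category;
#' caseloads are log-normal, optionally rank-correlated with process quality.
#'
#' @param config A [generator_config()].
#' @return A `region` object; `metadata` records the config, seed and extent.
#' @export
generate_region <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_region_impl(config))
}

generate_region_impl <- function(config) {
  half <- config$region_extent_km / 2
  anchor <- region_anchor()
  to_lon <- function(x_km) anchor[["lon"]] + x_km / km_per_deg_lon(anchor[["lat"]])
  to_lat <- function(y_km) anchor[["lat"]] + y_km / km_per_deg_lat
  runif_km <- function(n) cbind(runif(n, -half, half), runif(n, -half, half))

  district_xy <- runif_km(config$n_districts)
  district_ids <- sprintf("district_%02d", seq_len(config$n_districts))
  town_xy <- runif_km(config$n_towns)
  nearest_district <- function(xy) {
    d2 <- outer(xy[, 1], district_xy[, 1], "-")^2 +
      outer(xy[, 2], district_xy[, 2], "-")^2
    district_ids[max.col(-d2, ties.method = "first")]
  }

  # clusters
  cl_xy <- runif_km(config$n_clusters)
  clusters <- tibble(
    cluster_id = sprintf("C%03d", seq_len(config$n_clusters)),
    lon = to_lon(cl_xy[, 1]), lat = to_lat(cl_xy[, 2]),
    district = nearest_district(cl_xy),
    weight = config$weight
  )

  # facilities
  counts <- config$facility_counts[config$facility_counts > 0]
  n_fac <- sum(counts)
  category <- rep(names(counts), counts)
  town <- sample.int(config$n_towns, n_fac, replace = TRUE)
  spread <- config$region_extent_km / 12
  fac_xy <- cbind(
    pmin(half, pmax(-half, town_xy[town, 1] + rnorm(n_fac, 0, spread))),
    pmin(half, pmax(-half, town_xy[town, 2] + rnorm(n_fac, 0, spread)))
  )
  parts <- strsplit(category, ":", fixed = TRUE)
  facilities <- tibble(
    facility_id = sprintf("F%04d", seq_len(n_fac)),
    authority = vapply(parts, `[`, "", 1),
    level = vapply(parts, `[`, "", 2),
    district = nearest_district(fac_xy),
    lon = to_lon(fac_xy[, 1]), lat = to_lat(fac_xy[, 2]),
    skilled = TRUE
  )

  qp <- config$quality_params
  for (area in service_areas()) {
    for (ind in c("structural", "process")) {
      col <- score_col(ind, area)
      facilities[[col]] <- NA_real_
      for (cat in unique(category)) {
        p <- qp[qp$category == cat & qp$service_area == area, , drop = FALSE]
        if (nrow(p) == 0) {
          stop(sprintf("quality_params has no row for %s / %s", cat, area),
               call. = FALSE)
        }
        rows <- which(category == cat)
        facilities[[col]][rows] <- rbeta_ms(
          length(rows), p[[paste0(ind, "_mean")]][1],
          p[[paste0(ind, "_sd")]][1])
      }
    }
  }
  rho <- config$caseload_quality_correlation
  for (area in service_areas()) {
    z <- rnorm(n_fac)
    if (rho > 0) {
      q <- facilities[[score_col("process", area)]]
      zq <- qnorm((rank(q, ties.method = "random") - 0.5) / n_fac)
      z <- rho * zq + sqrt(1 - rho^2) * z
    }
    facilities[[caseload_col(area)]] <-
      exp(config$caseload_meanlog + config$caseload_sdlog * z)
  }
  facilities <- facilities[, facility_columns()]

  # episodes: each cluster has its own care-seeking propensity (Beta with
  # mean = configured total care-seeking probability and correlation
  # parameter care_seeking_icc), so design-based CIs show the large design
  # effects of a real regional cluster survey; the marginal source mix is
  # preserved exactly in expectation. Conditional on seeking, the source
  # category follows the configured mix.
  gen_episodes <- function(area, n_ep, prefix) {
    cl_idx <- sample.int(config$n_clusters, n_ep, replace = TRUE)
    mix <- config$category_mix[[area]]
    p_seek <- 1 - sum(mix[names(mix) == "none"])
    icc <- config$care_seeking_icc
    p_seek_c <- if (icc > 0 && p_seek > 0 && p_seek < 1) {
      rbeta(config$n_clusters,
            p_seek * (1 - icc) / icc, (1 - p_seek) * (1 - icc) / icc)
    } else {
      rep(p_seek, config$n_clusters)
    }
    seek <- runif(n_ep) < p_seek_c[cl_idx]
    mix_sought <- mix[names(mix) != "none"]
    mix_sought <- mix_sought / sum(mix_sought)
    cat1 <- rep("none", n_ep)
    if (any(seek)) {
      cat1[seek] <- sample_source_category(area, mix_sought, sum(seek))
    }
    rows <- tibble(
      episode_id = sprintf("%s%05d", prefix, seq_len(n_ep)),
      cluster_id = clusters$cluster_id[cl_idx],
      service_area = area,
      weight = config$weight,
      source_category = cat1
    )
    if (area == "sick_child" && config$p_second_source > 0) {
      extra <- which(seek & runif(n_ep) < config$p_second_source)
      if (length(extra) > 0) {
        rows <- bind_rows(rows, tibble(
          episode_id = rows$episode_id[extra],
          cluster_id = rows$cluster_id[extra],
          service_area = area,
          weight = config$weight,
          source_category = sample_source_category(area, mix_sought,
                                                   length(extra))
        ))
      }
    }
    rows
  }
  episodes <- bind_rows(
    gen_episodes("delivery", config$n_deliveries, "D"),
    gen_episodes("sick_child", config$n_sick_children, "S")
  )

  # stated providers via the gravity model, grouped by (category, cluster)
  episodes$stated_facility_id <- NA_character_
  needs_id <- which(episodes$source_category %in% facility_categories())
  if (length(needs_id) > 0) {
    key <- paste(episodes$source_category[needs_id],
                 episodes$cluster_id[needs_id],
                 episodes$service_area[needs_id], sep = "|")
    for (rows in split(needs_id, key)) {
      cat <- episodes$source_category[rows[1]]
      cl <- clusters[clusters$cluster_id == episodes$cluster_id[rows[1]], ]
      episodes$stated_facility_id[rows] <- sample_specific_provider(
        cl, cat, facilities, episodes$service_area[rows[1]],
        config$distance_decay_km, config$quality_preference,
        n = length(rows))
    }
  }

  extent <- list(lon = sort(to_lon(c(-half, half))),
                 lat = sort(to_lat(c(-half, half))))
  region <- region_dataset(
    facilities, clusters, episodes,
    metadata = list(seed = config$seed, config = config, extent = extent)
  )
  apply_unlinkable_mask(region, config$unlinkable_fraction)
}
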