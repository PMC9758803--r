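# SPA-style facility sampling and the two quality-score simulations.
#
# Sampling follows the Service Provision Assessment convention: referral
# facilities are enumerated completely in every draw, while first-level
# facilities are sampled without replacement, by default within two managing
# authority strata (public | non-public) with proportional allocation.
#
# Quality simulation "random" replaces every score with an independent
# uniform draw on [0, 1]. Quality simulation "preferential" shifts scores by
# a fixed delta (default 15 percentage points) to emulate preferential
# care-seeking from higher-quality providers: utilised facilities move up,
# unused facilities near a surveyed cluster move down, and remote unused
# facilities move up or down according to their standing relative to the
# category median.

#' Sample size for a proportion with finite-population correction
#'
#' Smallest n meeting the normal-approximation margin-of-error formula:
#' \eqn{n_0 = z^2 p (1-p) / e^2}, corrected as
#' \eqn{n = \lceil n_0 / (1 + (n_0 - 1)/N) \rceil}.
#'
#' @param n_frame Frame size N.
#' @param precision Half-width e of the interval, in (0, 1).
#' @param p Anticipated proportion (default 0.5, the conservative choice).
#' @param confidence Confidence level (default 0.95).
#' @return Required sample size (integer).
#' @export
spa_sample_size <- function(n_frame, precision, p = 0.5, confidence = 0.95) {
  if (precision <= 0 || precision >= 1) {
    stop("precision must lie strictly between 0 and 1", call. = FALSE)
  }
  stopifnot(n_frame >= 1, p > 0, p < 1)
  z <- qnorm(1 - (1 - confidence) / 2)
  n0 <- z^2 * p * (1 - p) / precision^2
  as.integer(ceiling(n0 / (1 + (n0 - 1) / n_frame)))
}

#' Facility sampling design
#'
#' @param sample_sizes First-level sample sizes to evaluate (default
#'   `c(65, 90, 130)`, the ±10%, ±7.5% and ±5% precision sizes).
#' @param n_draws Random draws per sample size (default 20).
#' @param stratify_by_authority Allocate the first-level sample across two
#'   managing-authority strata (public | non-public) proportionally; `FALSE`
#'   gives an unstratified simple random sample.
#' @param seed Master seed; each (size, draw) pair uses a deterministic
#'   sub-stream so any single draw is reproducible in isolation.
#' @return An object of class `sample_design`.
#' @export
sample_design <- function(sample_sizes = c(65, 90, 130), n_draws = 20,
                          stratify_by_authority = TRUE, seed = 1L) {
  stopifnot(all(sample_sizes >= 1), n_draws >= 1)
  structure(list(sample_sizes = as.integer(sample_sizes),
                 n_draws = as.integer(n_draws),
                 stratify_by_authority = isTRUE(stratify_by_authority),
                 seed = as.integer(seed)),
            class = "sample_design")
}

# Largest-remainder proportional allocation of n across strata of sizes N_h,
# capped at the stratum sizes.
allocate_proportional <- function(n_h, n) {
  q <- n * n_h / sum(n_h)
  alloc <- floor(q)
  rem <- n - sum(alloc)
  if (rem > 0) {
    ord <- order(q - alloc, n_h, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  while (any(alloc > n_h)) {
    over <- which(alloc > n_h)[1]
    surplus <- alloc[over] - n_h[over]
    alloc[over] <- n_h[over]
    room <- which(alloc < n_h)
    ord <- room[order(n_h[room] - alloc[room], decreasing = TRUE)]
    for (i in ord) {
      if (surplus == 0) break
      take <- min(surplus, n_h[i] - alloc[i])
      alloc[i] <- alloc[i] + take
      surplus <- surplus - take
    }
  }
  alloc
}

#' Draw one SPA-style facility sample
#'
#' Returns all referral facilities plus a without-replacement random sample
#' of `n` first-level facilities. With `design$stratify_by_authority`, `n` is
#' allocated proportionally across the public and non-public authority strata
#' (largest-remainder rounding) and drawn independently within each. The draw
#' is deterministic given `(design$seed, n, draw_index)`.
#'
#' @param census Facility tibble (the full census).
#' @param n Number of first-level facilities to sample.
#' @param design A [sample_design()].
#' @param draw_index Index of the draw (1-based).
#' @return Tibble of sampled facilities (referral census + first-level
#'   sample), sorted by `facility_id`.
#' @export
draw_facility_sample <- function(census, n, design = sample_design(),
                                 draw_index = 1L) {
  census <- as_tibble(census)
  first <- census %>%
    filter(.data$level == "first_level", .data$skilled) %>%
    arrange(.data$facility_id)
  referral <- census %>% filter(.data$level == "referral")
  if (n > nrow(first)) {
    stop(sprintf("requested n = %d exceeds the %d first-level facilities",
                 n, nrow(first)), call. = FALSE)
  }
  stratum <- if (design$stratify_by_authority) {
    ifelse(first$authority == "public", "public", "nonpublic")
  } else {
    rep("all", nrow(first))
  }
  strata <- sort(unique(stratum))
  n_h <- vapply(strata, function(s) sum(stratum == s), integer(1))
  alloc <- allocate_proportional(n_h, n)
  picked <- withr::with_seed(
    derive_seed(design$seed, n, draw_index),
    unlist(lapply(seq_along(strata), function(i) {
      idx <- which(stratum == strata[i])
      idx[sample.int(length(idx), alloc[i])]
    }))
  )
  bind_rows(referral, first[sort(picked), , drop = FALSE]) %>%
    arrange(.data$facility_id)
}

#' Replace facility quality scores with uniform random scores
#'
#' Every facility's structural and process score, for both service areas, is
#' replaced by an independent uniform draw on \[0, 1\]; locations, categories
#' and caseloads are untouched. Emulates a setting with maximal
#' within-category quality variability.
#'
#' @param census Facility tibble.
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return The census with new scores.
#' @export
assign_random_quality <- function(census, seed = NULL) {
  redraw <- function() {
    out <- as_tibble(census)
    for (col in facility_score_columns()) {
      out[[col]] <- runif(nrow(out))
    }
    out
  }
  if (is.null(seed)) redraw() else withr::with_seed(seed, redraw())
}

#' Facility utilization counts from the household survey
#'
#' Counts, per facility and service area, the distinct episodes whose
#' resolvable stated source of care is that facility.
#'
#' @param census Facility tibble.
#' @param episodes Episode tibble (one row per reported source).
#' @return Tibble with `facility_id`, `sick_child_users`, `delivery_users`
#'   covering every census facility (zeros where never stated).
#' @export
facility_utilization <- function(census, episodes) {
  counts <- as_tibble(episodes) %>%
    filter(!is.na(.data$stated_facility_id),
           .data$stated_facility_id %in% census$facility_id) %>%
    distinct(.data$episode_id, .data$service_area, .data$stated_facility_id) %>%
    count(.data$stated_facility_id, .data$service_area) %>%
    tidyr::pivot_wider(names_from = "service_area", values_from = "n",
                       values_fill = 0L)
  out <- tibble(facility_id = census$facility_id) %>%
    left_join(counts, by = c(facility_id = "stated_facility_id"))
  for (area in service_areas()) {
    col <- area
    if (!col %in% names(out)) out[[col]] <- 0L
    out[[col]][is.na(out[[col]])] <- 0L
  }
  out %>%
    transmute(.data$facility_id,
              sick_child_users = as.integer(.data$sick_child),
              delivery_users = as.integer(.data$delivery))
}

#' Minimum distance from facilities to any household cluster
#'
#' @param lon,lat Facility coordinates (vectorised).
#' @param clusters Cluster tibble with `lon`, `lat`.
#' @return Minimum great-circle distance in km, per facility.
#' @export
min_cluster_distance <- function(lon, lat, clusters) {
  if (nrow(clusters) == 0) {
    stop("at least one cluster is required", call. = FALSE)
  }
  d <- dist_matrix_km(lon, lat, clusters$lon, clusters$lat)
  apply(d, 1, min)
}

#' Quality-simulation configuration
#'
#' @param mode `"original"` (scores untouched), `"random"`
#'   ([assign_random_quality()]) or `"preferential"`
#'   ([apply_preferential_rules()]).
#' @param delta Score shift in the preferential rules, in score units
#'   (default 0.15, i.e. 15 percentage points).
#' @param distance_threshold_km Distance beyond which an unused facility is
#'   considered out of reach of the surveyed clusters (default 10 km).
#' @param min_users_sick_child,min_users_delivery Utilization thresholds: a
#'   facility counts as utilised with >= 1 sick-child user or >= 2 delivery
#'   users.
#' @param median_tie Direction applied when a remote unused facility's score
#'   equals the category median (`"up"`, the default, or `"down"`).
#' @param seed Seed for the random mode.
#' @return An object of class `quality_sim_config`.
#' @export
quality_sim_config <- function(mode = c("original", "random", "preferential"),
                               delta = 0.15, distance_threshold_km = 10,
                               min_users_sick_child = 1L,
                               min_users_delivery = 2L,
                               median_tie = c("up", "down"), seed = 1L) {
  mode <- match.arg(mode)
  median_tie <- match.arg(median_tie)
  stopifnot(delta > 0, delta < 1, distance_threshold_km > 0,
            min_users_sick_child >= 0, min_users_delivery >= 0)
  structure(list(mode = mode, delta = delta,
                 distance_threshold_km = distance_threshold_km,
                 min_users_sick_child = as.integer(min_users_sick_child),
                 min_users_delivery = as.integer(min_users_delivery),
                 median_tie = median_tie, seed = as.integer(seed)),
            class = "quality_sim_config")
}

#' Shift facility scores to emulate preferential care-seeking
#'
#' For each facility and each of the structural and process scores of one
#' service area: (i) facilities utilised at or above the service-area
#' threshold gain `delta`; (ii) under-utilised facilities within
#' `distance_threshold_km` of a surveyed cluster lose `delta`; (iii)
#' under-utilised facilities farther away gain `delta` if their pre-shift
#' score exceeds the provider-category median (computed on pre-shift scores)
#' and lose `delta` if below it (ties shift in the direction of
#' `config$median_tie`). Shifted scores are clamped to \[0, 1\].
#'
#' @param census Facility tibble.
#' @param episodes Episode tibble (provides utilization via stated ids).
#' @param clusters Cluster tibble.
#' @param config A [quality_sim_config()].
#' @param service_area Area whose two scores are shifted.
#' @return The census with shifted scores; attribute `shift_balance` holds
#'   the counts of facilities moved up and down per indicator.
#' @export
apply_preferential_rules <- function(census, episodes, clusters,
                                     config = quality_sim_config("preferential"),
                                     service_area = c("sick_child", "delivery")) {
  service_area <- match.arg(service_area)
  census <- as_tibble(census)
  util <- facility_utilization(census, episodes)
  users <- util[[paste0(service_area, "_users")]][
    match(census$facility_id, util$facility_id)]
  threshold <- if (service_area == "sick_child") {
    config$min_users_sick_child
  } else {
    config$min_users_delivery
  }
  dmin <- min_cluster_distance(census$lon, census$lat, clusters)
  category <- fac_category(census)

  balance <- NULL
  out <- census
  for (ind in c("structural", "process")) {
    col <- score_col(ind, service_area)
    s <- census[[col]]
    med <- ave(s, category, FUN = median)
    above <- if (config$median_tie == "up") s >= med else s > med
    shift <- ifelse(
      users >= threshold, config$delta,
      ifelse(dmin <= config$distance_threshold_km, -config$delta,
             ifelse(above, config$delta, -config$delta)))
    out[[col]] <- pmin(1, pmax(0, s + shift))
    balance <- bind_rows(balance, tibble(
      service_area = service_area, indicator = ind,
      n_up = sum(shift > 0), n_down = sum(shift < 0)))
  }
  prior <- attr(census, "shift_balance")
  attr(out, "shift_balance") <- bind_rows(prior, balance)
  out
}
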