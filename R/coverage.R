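# Effective coverage cascades: crude care-seeking coverage, input-adjusted
# coverage (discounted by the structural quality of the linked provider), and
# quality-adjusted coverage (discounted by process quality). Variances are
# design-based, with household clusters as primary sampling units in a single
# stratum; the linked provider scores are treated as an extension of the
# household dataset, so error in the facility assessment is ignored by
# construction.

#' Design-based standard error and confidence interval for a weighted mean
#'
#' Taylor linearization of the weighted ratio mean with clusters as PSUs
#' (single stratum, with-replacement approximation): with
#' \eqn{\hat R = \sum w_i v_i / \sum w_i} and cluster totals
#' \eqn{u_c = \sum_{i \in c} w_i (v_i - \hat R)},
#' \eqn{\widehat{var}(\hat R) = \frac{n}{n-1} \sum_c (u_c - \bar u)^2 /
#' (\sum w_i)^2} where \eqn{n} is the number of clusters. The symmetric
#' interval uses a t quantile with \eqn{n - 1} degrees of freedom and is
#' clipped to \[0, 1\].
#'
#' @param values Data frame with columns `cluster_id`, `weight`, `value`
#'   (one row per episode).
#' @param level Confidence level (default 0.95).
#' @return List with `point`, `se`, `ci_low`, `ci_high`, `n_clusters`.
#' @export
design_ci <- function(values, level = 0.95) {
  stopifnot(all(c("cluster_id", "weight", "value") %in% names(values)))
  n_cl <- dplyr::n_distinct(values$cluster_id)
  if (n_cl < 2) {
    stop("design-based variance requires at least 2 clusters", call. = FALSE)
  }
  w <- values$weight
  v <- values$value
  W <- sum(w)
  point <- sum(w * v) / W
  u <- tapply(w * (v - point), values$cluster_id, sum)
  vr <- n_cl / (n_cl - 1) * sum((u - mean(u))^2) / W^2
  se <- sqrt(vr)
  tq <- qt(1 - (1 - level) / 2, df = n_cl - 1)
  list(point = point, se = se,
       ci_low = max(0, point - tq * se),
       ci_high = min(1, point + tq * se),
       n_clusters = n_cl)
}

episode_frame <- function(region, service_area) {
  region$episodes %>%
    filter(.data$service_area == !!service_area) %>%
    distinct(.data$episode_id, .data$cluster_id, .data$weight)
}

#' Effective coverage from linked quality scores
#'
#' Computes \eqn{\sum_i w_i s_i q_i / \sum_i w_i} over in-need episodes of a
#' service area, where \eqn{s_i} indicates skilled care sought and \eqn{q_i}
#' is the linked structural score (`input_adjusted`), process score
#' (`quality_adjusted`), or 1 (`crude`). The standard error and confidence
#' interval come from [design_ci()].
#'
#' @param region A `region` object.
#' @param links Output of [link_episodes()] covering every in-need episode of
#'   the service area.
#' @param indicator `"crude"`, `"input_adjusted"` or `"quality_adjusted"`.
#' @param service_area Defaults to the area carried by `links`.
#' @param level Confidence level.
#' @param dataset_tag Identity of the facility dataset behind `links`
#'   (`"census"`, `"exact"`, or a sample draw tag).
#' @return One-row tibble: `indicator`, `service_area`, `method`, `dataset`,
#'   `point`, `se`, `ci_low`, `ci_high`, `n_episodes`, `n_clusters`.
#' @export
effective_coverage <- function(region, links,
                               indicator = c("crude", "input_adjusted",
                                             "quality_adjusted"),
                               service_area = unique(links$service_area),
                               level = 0.95, dataset_tag = "census") {
  indicator <- match.arg(indicator)
  stopifnot(length(service_area) == 1)
  eps <- episode_frame(region, service_area)
  missing <- setdiff(eps$episode_id, links$episode_id)
  if (length(missing) > 0) {
    stop(sprintf("no link result for in-need episode(s): %s",
                 paste(head(missing, 3), collapse = ", ")), call. = FALSE)
  }
  d <- eps %>% left_join(links, by = "episode_id")
  q <- switch(indicator,
              crude = rep(1, nrow(d)),
              input_adjusted = d$structural,
              quality_adjusted = d$process)
  value <- ifelse(d$skilled_care, q, 0)
  if (anyNA(value)) {
    stop("missing linked score for an episode with skilled care",
         call. = FALSE)
  }
  ci <- design_ci(tibble(cluster_id = d$cluster_id, weight = d$weight,
                         value = value), level = level)
  tibble(
    indicator = indicator,
    service_area = service_area,
    method = unique(links$method)[1],
    dataset = dataset_tag,
    point = ci$point, se = ci$se,
    ci_low = ci$ci_low, ci_high = ci$ci_high,
    n_episodes = nrow(d), n_clusters = ci$n_clusters
  )
}

#' Crude coverage of care-seeking
#'
#' The weighted proportion of in-need episodes for which care was sought.
#' With `skilled_only = TRUE` (the default) only facility-based (skilled)
#' sources count — pharmacies and community health workers are treated as
#' unskilled providers; with `skilled_only = FALSE` any reported source
#' counts as care sought.
#'
#' @param region A `region` object.
#' @param service_area `"sick_child"` or `"delivery"`.
#' @param skilled_only Count only skilled (facility) sources.
#' @param level Confidence level.
#' @return One-row tibble in the [effective_coverage()] layout.
#' @export
crude_coverage <- function(region, service_area = c("sick_child", "delivery"),
                           skilled_only = TRUE, level = 0.95) {
  service_area <- match.arg(service_area)
  eps <- episode_frame(region, service_area)
  excluded <- if (skilled_only) c("none", "unskilled") else "none"
  seekers <- region$episodes %>%
    filter(.data$service_area == !!service_area,
           !(.data$source_category %in% excluded)) %>%
    pull(.data$episode_id) %>%
    unique()
  value <- as.numeric(eps$episode_id %in% seekers)
  ci <- design_ci(tibble(cluster_id = eps$cluster_id, weight = eps$weight,
                         value = value), level = level)
  tibble(
    indicator = "crude",
    service_area = service_area,
    method = "none",
    dataset = "survey",
    point = ci$point, se = ci$se,
    ci_low = ci$ci_low, ci_high = ci$ci_high,
    n_episodes = nrow(eps), n_clusters = ci$n_clusters
  )
}
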