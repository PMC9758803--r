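# Scenario runner: orchestrates one full simulation scenario and produces
# the grid of sample-derived estimates together with their census and
# exact-match references, outlier counts, and summary tables.
#
# Under the default design (2 ecological methods x sample sizes {65, 90, 130}
# x 20 draws x 2 service areas x 2 adjusted indicators) a scenario yields 480
# sampled estimates: 160 per sample size and 240 per linking method.

ecological_methods <- function() c("euclidean", "admin")
adjusted_indicators <- function() c("input_adjusted", "quality_adjusted")

#' Run one simulation scenario
#'
#' Applies the scenario's quality treatment to the census (`original`: none;
#' `random`: [assign_random_quality()]; `preferential`:
#' [apply_preferential_rules()] for both service areas), computes exact-match
#' references on the (re-scored) census and census references for each
#' ecological method, then applies both ecological methods to every sampled
#' facility set in the design grid, for both service areas and both adjusted
#' indicators. Exact-match references are recomputed on the re-scored census
#' so that every scenario is compared against its own truth.
#'
#' @param region A `region` object.
#' @param scenario `"original"`, `"random"` or `"preferential"`.
#' @param design A [sample_design()].
#' @param qconfig A [quality_sim_config()]; defaults to the scenario's mode.
#' @return An object of class `scenario_result`: list with `scenario`,
#'   `estimates` (tidy tibble of every estimate), `outliers` (counts by
#'   margin and reference), `summaries` (median and IQR per grid cell),
#'   `shift_balance` (preferential scenario only), `design`, `qconfig`.
#' @export
run_scenario <- function(region,
                         scenario = c("original", "random", "preferential"),
                         design = sample_design(), qconfig = NULL) {
  stopifnot(inherits(region, "region"))
  scenario <- match.arg(scenario)
  if (is.null(qconfig)) qconfig <- quality_sim_config(scenario)
  stopifnot(inherits(design, "sample_design"),
            inherits(qconfig, "quality_sim_config"))

  census <- region$facilities
  shift_balance <- NULL
  if (scenario == "random") {
    census <- assign_random_quality(census, seed = qconfig$seed)
  } else if (scenario == "preferential") {
    for (area in service_areas()) {
      census <- apply_preferential_rules(census, region$episodes,
                                         region$clusters, qconfig, area)
    }
    shift_balance <- attr(census, "shift_balance")
  }
  scored <- region
  scored$facilities <- census

  est <- list()
  push <- function(x, size = NA_integer_, draw = NA_integer_) {
    x$sample_size <- as.integer(size)
    x$draw_index <- as.integer(draw)
    est[[length(est) + 1]] <<- x
  }

  for (area in service_areas()) {
    links <- link_episodes(scored, "exact", area)
    for (ind in adjusted_indicators()) {
      push(effective_coverage(scored, links, ind, area,
                              dataset_tag = "exact"))
    }
    for (m in ecological_methods()) {
      links <- link_episodes(scored, m, area)
      for (ind in adjusted_indicators()) {
        push(effective_coverage(scored, links, ind, area,
                                dataset_tag = "census"))
      }
    }
  }

  for (size in design$sample_sizes) {
    for (d in seq_len(design$n_draws)) {
      fac_sample <- draw_facility_sample(census, size, design, d)
      for (m in ecological_methods()) {
        for (area in service_areas()) {
          links <- link_episodes(scored, m, area, facilities = fac_sample)
          for (ind in adjusted_indicators()) {
            push(effective_coverage(scored, links, ind, area,
                                    dataset_tag = "sample"),
                 size = size, draw = d)
          }
        }
      }
    }
  }

  estimates <- bind_rows(est) %>%
    mutate(scenario = scenario, .before = 1)

  structure(
    list(scenario = scenario,
         estimates = estimates,
         outliers = outlier_table(estimates),
         summaries = summarize_estimates(estimates),
         shift_balance = shift_balance,
         design = design,
         qconfig = qconfig),
    class = "scenario_result"
  )
}

#' Count sampled estimates outside a reference confidence interval
#'
#' Strict inequality: a point equal to a bound is not an outlier.
#'
#' @param points Numeric vector of sampled point estimates.
#' @param ci_low,ci_high Reference interval bounds (scalars).
#' @return Integer count.
#' @export
count_outliers <- function(points, ci_low, ci_high) {
  stopifnot(length(ci_low) == 1, length(ci_high) == 1)
  sum(points < ci_low | points > ci_high)
}

# Sampled estimates joined with their exact-match and census references and
# per-estimate outlier flags.
flag_outliers <- function(estimates) {
  sampled <- estimates %>% filter(.data$dataset == "sample")
  exact_ref <- estimates %>%
    filter(.data$dataset == "exact") %>%
    select("service_area", "indicator",
           exact_low = "ci_low", exact_high = "ci_high")
  census_ref <- estimates %>%
    filter(.data$dataset == "census") %>%
    select("method", "service_area", "indicator",
           census_low = "ci_low", census_high = "ci_high")
  sampled %>%
    left_join(exact_ref, by = c("service_area", "indicator")) %>%
    left_join(census_ref, by = c("method", "service_area", "indicator")) %>%
    mutate(
      outlier_vs_exact = .data$point < .data$exact_low |
        .data$point > .data$exact_high,
      outlier_vs_census = .data$point < .data$census_low |
        .data$point > .data$census_high
    )
}

outlier_table <- function(estimates) {
  flagged <- flag_outliers(estimates)
  tally <- function(grouped, margin) {
    grouped %>%
      summarise(
        n_estimates = n(),
        outliers_vs_exact = sum(.data$outlier_vs_exact),
        outliers_vs_census = sum(.data$outlier_vs_census),
        .groups = "drop"
      ) %>%
      mutate(margin = margin, .before = 1)
  }
  bind_rows(
    tally(flagged %>% group_by(level = as.character(.data$sample_size)),
          "sample_size"),
    tally(flagged %>% group_by(level = .data$method), "method"),
    tally(flagged %>% mutate(level = "all") %>% group_by(.data$level),
          "total")
  ) %>%
    mutate(pct_vs_exact = 100 * .data$outliers_vs_exact / .data$n_estimates,
           pct_vs_census = 100 * .data$outliers_vs_census / .data$n_estimates)
}

#' Median and interquartile range of sampled estimates per grid cell
#'
#' One row per (service area, indicator, linking method, sample size), with
#' the median and 25th/75th percentiles (linear interpolation, `type = 7`) of
#' the sampled point estimates.
#'
#' @param estimates Estimates tibble from [run_scenario()] (reference rows
#'   are ignored), or any tibble of sampled estimates in the same layout.
#' @return Tibble of summaries.
#' @export
summarize_estimates <- function(estimates) {
  sampled <- estimates
  if ("dataset" %in% names(sampled)) {
    sampled <- sampled %>% filter(.data$dataset == "sample")
  }
  if (nrow(sampled) == 0) {
    stop("no sampled estimates to summarise", call. = FALSE)
  }
  sampled %>%
    group_by(.data$service_area, .data$indicator, .data$method,
             .data$sample_size) %>%
    summarise(
      n = n(),
      median = median(.data$point),
      iqr_low = unname(quantile(.data$point, 0.25, type = 7)),
      iqr_high = unname(quantile(.data$point, 0.75, type = 7)),
      .groups = "drop"
    )
}

#' Export a scenario report
#'
#' Writes `estimates.csv` (every estimate, tidy), `outliers.csv` (counts and
#' percentages by sample size, by linking method, and in total — the per-size
#' denominator is methods x draws x areas x indicators, the per-method
#' denominator sizes x draws x areas x indicators), `summary.csv` (median and
#' IQR per grid cell, in percent to one decimal), and one strip plot per
#' service area showing the exact-match CI band, the census estimates with
#' CIs, and the sampled points.
#'
#' @param result A `scenario_result`.
#' @param directory Output directory.
#' @return Invisibly, the paths written.
#' @export
export_report <- function(result, directory) {
  stopifnot(inherits(result, "scenario_result"))
  dir.create(file.path(directory, "plots"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- c(estimates = file.path(directory, "estimates.csv"),
             outliers = file.path(directory, "outliers.csv"),
             summary = file.path(directory, "summary.csv"))
  readr::write_csv(result$estimates, paths[["estimates"]], progress = FALSE)
  readr::write_csv(result$outliers, paths[["outliers"]], progress = FALSE)
  summary_pct <- result$summaries %>%
    mutate(across(c("median", "iqr_low", "iqr_high"),
                  ~ round(100 * .x, 1)))
  readr::write_csv(summary_pct, paths[["summary"]], progress = FALSE)

  for (area in unique(result$estimates$service_area)) {
    p <- plot_scenario_strips(result, area)
    f <- file.path(directory, "plots",
                   sprintf("%s_%s.png", result$scenario, area))
    ggplot2::ggsave(f, p, width = 8, height = 5, dpi = 150)
    paths[[paste0("plot_", area)]] <- f
  }
  invisible(paths)
}

plot_scenario_strips <- function(result, area) {
  est <- result$estimates %>% filter(.data$service_area == area)
  sampled <- est %>%
    filter(.data$dataset == "sample") %>%
    mutate(x = factor(.data$sample_size))
  census <- est %>%
    filter(.data$dataset == "census") %>%
    mutate(x = factor("census", levels = c("census",
                                           levels(sampled$x))))
  sampled$x <- factor(sampled$x, levels = levels(census$x))
  exact <- est %>% filter(.data$dataset == "exact")
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = exact,
      ggplot2::aes(xmin = -Inf, xmax = Inf, ymin = .data$ci_low,
                   ymax = .data$ci_high),
      fill = "red", alpha = 0.08) +
    ggplot2::geom_hline(data = exact,
                        ggplot2::aes(yintercept = .data$point),
                        colour = "red") +
    ggplot2::geom_errorbar(
      data = census,
      ggplot2::aes(x = .data$x, ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.2, colour = "steelblue") +
    ggplot2::geom_point(data = census,
                        ggplot2::aes(x = .data$x, y = .data$point),
                        colour = "steelblue", size = 2) +
    ggplot2::geom_jitter(data = sampled,
                         ggplot2::aes(x = .data$x, y = .data$point),
                         width = 0.15, height = 0, colour = "grey40",
                         size = 0.8, alpha = 0.7) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$indicator),
      cols = ggplot2::vars(.data$method)) +
    ggplot2::labs(
      x = "facility dataset (census / first-level sample size)",
      y = "effective coverage",
      title = sprintf("%s care, %s scenario", gsub("_", " ", area),
                      result$scenario),
      subtitle = "red: exact-match estimate and 95% CI; blue: census ecological estimate; grey: sampled estimates") +
    ggplot2::theme_minimal(base_size = 10)
}

#' @export
print.scenario_result <- function(x, ...) {
  total <- x$outliers[x$outliers$margin == "total", , drop = FALSE]
  cat(sprintf("<scenario_result> scenario = %s\n", x$scenario))
  cat(sprintf("  %d sampled estimates (%s sizes x %d draws)\n",
              sum(x$estimates$dataset == "sample"),
              paste(x$design$sample_sizes, collapse = "/"),
              x$design$n_draws))
  if (nrow(total) == 1) {
    cat(sprintf("  outliers vs exact-match CI: %d (%.1f%%); vs census CI: %d (%.1f%%)\n",
                total$outliers_vs_exact, total$pct_vs_exact,
                total$outliers_vs_census, total$pct_vs_census))
  }
  invisible(x)
}
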