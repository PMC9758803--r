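test_that("the finite-population sample-size formula evaluates correctly", {
  # n0 = 1.96^2 * 0.25 / 0.1^2 = 96.04; FPC against N = 187 gives 64
  expect_equal(spa_sample_size(187, 0.10), 64L)
  # negligible FPC for a large frame
  expect_equal(spa_sample_size(10000, 0.10), 96L)
  # very loose precision needs a single facility
  expect_equal(spa_sample_size(187, 0.99), 1L)
  expect_error(spa_sample_size(187, 1), "precision")
  expect_error(spa_sample_size(187, 0), "precision")
})

synthetic_census <- function(n_public = 150, n_private = 25, n_religious = 12,
                             n_referral = 7, seed = 17) {
  withr::with_seed(seed, dplyr::bind_rows(
    mk_fac(sprintf("P%03d", 1:n_public), lon = runif(n_public),
           lat = runif(n_public), structural = runif(n_public),
           process = runif(n_public)),
    mk_fac(sprintf("V%03d", 1:n_private), authority = "private",
           lon = runif(n_private), lat = runif(n_private),
           structural = runif(n_private), process = runif(n_private)),
    mk_fac(sprintf("R%03d", 1:n_religious), authority = "religious",
           lon = runif(n_religious), lat = runif(n_religious),
           structural = runif(n_religious), process = runif(n_religious)),
    mk_fac(sprintf("H%03d", 1:n_referral), level = "referral",
           lon = runif(n_referral), lat = runif(n_referral),
           structural = runif(n_referral), process = runif(n_referral))
  ))
}

test_that("facility samples keep the referral census and the requested first-level count", {
  census <- synthetic_census()  # 187 first-level + 7 referral
  design <- sample_design(seed = 5)
  s <- draw_facility_sample(census, 65, design, 1)
  expect_equal(nrow(s), 72)
  expect_true(all(census$facility_id[census$level == "referral"] %in%
                    s$facility_id))
  expect_equal(sum(s$level == "first_level"), 65)
  expect_false(any(duplicated(s$facility_id)))

  # exhaustive sample equals the census
  s_all <- draw_facility_sample(census, 187, design, 1)
  expect_equal(sort(s_all$facility_id), sort(census$facility_id))

  # deterministic per (seed, n, draw); distinct draws differ
  expect_identical(draw_facility_sample(census, 65, design, 3),
                   draw_facility_sample(census, 65, design, 3))
  expect_false(identical(draw_facility_sample(census, 65, design, 1),
                         draw_facility_sample(census, 65, design, 2)))

  expect_error(draw_facility_sample(census, 188, design, 1), "exceeds")
})

test_that("stratified allocation gives every first-level facility ~n/N inclusion probability", {
  census <- synthetic_census()
  design <- sample_design(seed = 11)
  first <- census[census$level == "first_level", ]
  hits <- setNames(numeric(nrow(first)), first$facility_id)
  n_draws <- 3000
  for (d in seq_len(n_draws)) {
    s <- draw_facility_sample(census, 65, design, d)
    ids <- s$facility_id[s$level == "first_level"]
    hits[ids] <- hits[ids] + 1
  }
  freq <- hits / n_draws
  # stratum shares under proportional allocation: 52/150 public, 13/37 other
  share <- ifelse(first$authority == "public", 52 / 150, 13 / 37)
  # every stratum's total inclusion is deterministic ...
  expect_equal(sum(freq[first$authority == "public"]), 52)
  expect_equal(sum(freq[first$authority != "public"]), 13)
  # ... and each facility's frequency is close to its stratum share
  # (4 pp ~ 4.6 Monte-Carlo standard errors at 3000 draws)
  expect_true(all(abs(freq - share) < 0.04))
  expect_true(all(abs(share - 65 / 187) < 0.01))
})

test_that("random quality reassignment changes only the scores", {
  census <- synthetic_census()
  r1 <- assign_random_quality(census, seed = 3)
  r2 <- assign_random_quality(census, seed = 3)
  expect_identical(r1, r2)
  score_cols <- c("structural_sick_child", "structural_delivery",
                  "process_sick_child", "process_delivery")
  for (col in score_cols) {
    expect_true(all(r1[[col]] >= 0 & r1[[col]] <= 1))
  }
  other <- setdiff(names(census), score_cols)
  expect_identical(r1[other], census[other])
  # the two numerous first-level categories centre near 0.5
  for (auth in c("public", "private")) {
    sub <- r1[r1$authority == auth & r1$level == "first_level", ]
    expect_equal(median(sub$structural_delivery), 0.5, tolerance = 0.1 / 0.5)
  }
})

test_that("facility utilization counts distinct resolvable stated episodes", {
  census <- dplyr::bind_rows(mk_fac("F1"), mk_fac("F2"))
  eps <- dplyr::bind_rows(
    mk_ep("S1", area = "sick_child", stated = "F1"),
    mk_ep("S2", area = "sick_child", stated = "F1"),
    mk_ep("S2", area = "sick_child", stated = "F1"),  # second source, same fac
    mk_ep("D1", stated = "F2"),
    mk_ep("D2", stated = "F_UNKNOWN"),                # unresolvable
    mk_ep("D3", category = "none")
  )
  u <- facility_utilization(census, eps)
  expect_equal(u$sick_child_users[u$facility_id == "F1"], 2L)
  expect_equal(u$delivery_users[u$facility_id == "F1"], 0L)
  expect_equal(u$delivery_users[u$facility_id == "F2"], 1L)
  # conservation: totals equal resolvable care-seeking episodes per area
  expect_equal(sum(u$sick_child_users), 2L)
  expect_equal(sum(u$delivery_users), 1L)
})

test_that("minimum cluster distance behaves like a minimum of haversines", {
  cls <- dplyr::bind_rows(mk_cluster("C1"), mk_cluster("C2", lat = 1))
  expect_equal(min_cluster_distance(0, 0, cls), 0)
  expect_equal(min_cluster_distance(0, 2, cls), 111.195,
               tolerance = 0.01 / 111.195)
  d <- min_cluster_distance(0.3, 0.7, cls)
  expect_lte(d, distance_km(0.3, 0.7, 0, 0))
  expect_lte(d, distance_km(0.3, 0.7, 0, 1))
  expect_error(min_cluster_distance(0, 0, cls[0, ]), "at least one cluster")
})

test_that("preferential rules shift scores by the configured delta", {
  cfg <- quality_sim_config("preferential")
  cls <- mk_cluster("C1")
  census <- dplyr::bind_rows(
    mk_fac("F1", lat = 0.01, structural = 0.50, process = 0.50),  # used
    mk_fac("F2", lat = 4 / 111.195, structural = 0.50, process = 0.50),
    mk_fac("F3", lat = 25 / 111.195, structural = 0.70, process = 0.70),
    mk_fac("F4", lat = 25.5 / 111.195, structural = 0.40, process = 0.40),
    mk_fac("F5", lat = 26 / 111.195, structural = 0.60, process = 0.60)
  )
  # category medians (pre-shift): structural 0.50 -> F3 above, F4 below

  # sick child: one user is enough to count as utilised
  eps_sc <- mk_ep("S1", area = "sick_child", stated = "F1")
  out <- apply_preferential_rules(census, eps_sc, cls, cfg, "sick_child")
  expect_equal(out$structural_sick_child[out$facility_id == "F1"], 0.65)
  expect_equal(out$structural_sick_child[out$facility_id == "F2"], 0.35)
  expect_equal(out$structural_sick_child[out$facility_id == "F3"], 0.85)
  expect_equal(out$structural_sick_child[out$facility_id == "F4"], 0.25)
  # remaining scores untouched in the other service area
  expect_identical(out$structural_delivery, census$structural_delivery)

  # delivery: a single user is below the 2-user threshold
  eps_d <- mk_ep("D1", stated = "F2")
  out_d <- apply_preferential_rules(census, eps_d, cls, cfg, "delivery")
  expect_equal(out_d$structural_delivery[out_d$facility_id == "F2"], 0.35)
  eps_d2 <- dplyr::bind_rows(mk_ep("D1", stated = "F2"),
                             mk_ep("D2", stated = "F2"))
  out_d2 <- apply_preferential_rules(census, eps_d2, cls, cfg, "delivery")
  expect_equal(out_d2$structural_delivery[out_d2$facility_id == "F2"], 0.65)

  # shifted scores never leave [0, 1]
  extreme <- dplyr::bind_rows(
    mk_fac("H1", lat = 0.01, structural = 0.95, process = 0.95),
    mk_fac("H2", lat = 0.02, structural = 0.05, process = 0.05)
  )
  eps_h <- mk_ep("S1", area = "sick_child", stated = "H1")
  out_h <- apply_preferential_rules(extreme, eps_h, cls, cfg, "sick_child")
  expect_equal(out_h$structural_sick_child, c(1, 0))

  # interior shifts have magnitude delta
  moved <- abs(out$structural_sick_child - census$structural_sick_child)
  interior <- out$structural_sick_child > 0 & out$structural_sick_child < 1
  expect_equal(moved[interior], rep(0.15, sum(interior)))

  # balance diagnostic records up/down counts
  bal <- attr(out, "shift_balance")
  expect_equal(sum(bal$n_up + bal$n_down), 2 * nrow(census))
})
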