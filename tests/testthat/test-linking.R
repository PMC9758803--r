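test_that("great-circle distance matches the haversine closed form", {
  expect_equal(distance_km(3, 7, 3, 7), 0)
  # one degree of latitude at the mean Earth radius
  expect_equal(distance_km(0, 0, 0, 1), 111.195, tolerance = 0.01 / 111.195)
  set.seed(11)
  lon1 <- runif(20, -180, 180); lat1 <- runif(20, -90, 90)
  lon2 <- runif(20, -180, 180); lat2 <- runif(20, -90, 90)
  expect_equal(distance_km(lon1, lat1, lon2, lat2),
               distance_km(lon2, lat2, lon1, lat1))
  expect_equal(distance_km(lon1, lat1, lon2, lat2),
               oracle_hav(lon1, lat1, lon2, lat2), tolerance = 1e-9)
  expect_error(distance_km(0, 95, 0, 0), "latitude")
})

linking_fixture <- function() {
  facs <- dplyr::bind_rows(
    # ~3 km and ~8 km north of cluster C1, same category
    mk_fac("F1", lat = 3 / 111.195, structural = 0.2, process = 0.2,
           caseload = 100),
    mk_fac("F2", lat = 8 / 111.195, structural = 0.9, process = 0.6,
           caseload = 300),
    mk_fac("F3", authority = "private", district = "d2", lon = 1, lat = 1,
           structural = 0.6, process = 0.4, caseload = 50),
    mk_fac("F4", level = "referral", lon = 0.5, lat = 0.5,
           structural = 0.7, process = 0.3, caseload = 10)
  )
  cls <- dplyr::bind_rows(mk_cluster("C1"),
                          mk_cluster("C2", lon = 1, lat = 1, district = "d2"))
  list(facs = facs, cls = cls)
}

test_that("exact-match linking uses the stated facility and falls back on unresolvable ids", {
  fx <- linking_fixture()
  eps <- dplyr::bind_rows(
    mk_ep("E1", stated = "F1"),
    mk_ep("E2", stated = "F_GONE"),                      # unresolvable
    mk_ep("E3", area = "sick_child", category = "unskilled"),
    mk_ep("E4", category = "none")
  )
  r <- mk_region(fx$facs, fx$cls, eps)
  l <- link_episodes(r, "exact", "delivery")

  e1 <- l[l$episode_id == "E1", ]
  expect_equal(e1$structural, 0.2)
  expect_equal(e1$process, 0.2)
  expect_false(e1$fallback_used)
  expect_equal(e1$linked_facilities, "F1")

  # fallback: caseload-weighted category mean (0.2*100 + 0.9*300) / 400
  e2 <- l[l$episode_id == "E2", ]
  expect_true(e2$fallback_used)
  expect_equal(e2$linked_facilities, "")
  expect_equal(e2$structural, 0.725)
  expect_equal(e2$process, (0.2 * 100 + 0.6 * 300) / 400)

  e4 <- l[l$episode_id == "E4", ]
  expect_false(e4$skilled_care)
  expect_true(is.na(e4$structural))

  ls <- link_episodes(r, "exact", "sick_child")
  e3 <- ls[ls$episode_id == "E3", ]
  expect_false(e3$skilled_care)
  expect_true(is.na(e3$structural) && is.na(e3$process))
})

test_that("euclidean linking picks the nearest facility of the reported category", {
  fx <- linking_fixture()
  eps <- mk_ep("E1")
  r <- mk_region(fx$facs, fx$cls, eps)
  l <- link_episodes(r, "euclidean", "delivery")
  expect_equal(l$linked_facilities, "F1")  # 3 km beats 8 km despite lower score
  expect_equal(l$structural, 0.2)

  # a single facility of the category links regardless of distance
  eps2 <- mk_ep("E1", cluster = "C2", category = "public:referral")
  l2 <- link_episodes(mk_region(fx$facs, fx$cls, eps2), "euclidean",
                      "delivery")
  expect_equal(l2$linked_facilities, "F4")

  # equidistant tie broken by smallest facility_id
  tie_facs <- dplyr::bind_rows(
    mk_fac("FB", lat = 0.1, structural = 0.9),
    mk_fac("FA", lat = -0.1, structural = 0.1)
  )
  lt <- link_episodes(mk_region(tie_facs, mk_cluster("C1"), mk_ep("E1")),
                      "euclidean", "delivery")
  expect_equal(lt$linked_facilities, "FA")
})

test_that("euclidean linking on a sample falls back to the category mean when the category is absent", {
  fx <- linking_fixture()
  eps <- mk_ep("E1", cluster = "C2", category = "private:first_level")
  r <- mk_region(fx$facs, fx$cls, eps)
  sample_no_private <- fx$facs[fx$facs$authority != "private", ]
  l <- link_episodes(r, "euclidean", "delivery",
                     facilities = sample_no_private)
  expect_true(l$fallback_used)
  expect_equal(l$structural, 0.6)  # census-wide private mean (only F3)
})

test_that("admin linking assigns the caseload-weighted district-category mean", {
  fx <- linking_fixture()
  eps <- mk_ep("E1")
  r <- mk_region(fx$facs, fx$cls, eps)
  l <- link_episodes(r, "admin", "delivery")
  expect_equal(l$structural, (0.2 * 100 + 0.9 * 300) / 400)  # = 0.725
  expect_equal(l$linked_facilities, "F1;F2")
  expect_false(l$fallback_used)

  # hand-computed example: scores 0.2 / 0.6, caseloads 100 / 300 -> 0.5
  facs2 <- dplyr::bind_rows(
    mk_fac("G1", structural = 0.2, caseload = 100),
    mk_fac("G2", structural = 0.6, caseload = 300)
  )
  l2 <- link_episodes(mk_region(facs2, mk_cluster("C1"), mk_ep("E1")),
                      "admin", "delivery")
  expect_equal(l2$structural, 0.5)

  # equal caseloads degrade to the unweighted mean
  facs3 <- dplyr::bind_rows(
    mk_fac("G1", structural = 0.2, caseload = 70),
    mk_fac("G2", structural = 0.6, caseload = 70)
  )
  l3 <- link_episodes(mk_region(facs3, mk_cluster("C1"), mk_ep("E1")),
                      "admin", "delivery")
  expect_equal(l3$structural, 0.4)
})

test_that("admin linking falls back to the set-wide category average when the district is empty", {
  fx <- linking_fixture()
  # C2 (district d2) reports public first-level care, but d2 has none
  eps <- mk_ep("E1", cluster = "C2")
  r <- mk_region(fx$facs, fx$cls, eps)
  l <- link_episodes(r, "admin", "delivery")
  expect_true(l$fallback_used)
  expect_equal(l$structural, 0.725)  # region-wide caseload-weighted mean
})

test_that("fallback_score averages over the category and escalates to the census", {
  fx <- linking_fixture()
  fb <- fallback_score("public:referral", fx$facs, "delivery")
  expect_equal(fb$structural, 0.7)
  expect_equal(fb$process, 0.3)
  expect_false(fb$from_census)

  two <- dplyr::bind_rows(mk_fac("A", structural = 0.4),
                          mk_fac("B", structural = 0.8))
  expect_equal(fallback_score("public:first_level", two,
                              "delivery")$structural, 0.6)

  sample_no_private <- fx$facs[fx$facs$authority != "private", ]
  fb2 <- fallback_score("private:first_level", sample_no_private, "delivery",
                        census = fx$facs)
  expect_true(fb2$from_census)
  expect_equal(fb2$structural, 0.6)

  expect_error(fallback_score("ngo:referral", fx$facs, "delivery",
                              census = fx$facs), "no facility of category")
})

test_that("multi-source sick-child episodes average their skilled sources; unskilled ones are ignored", {
  one <- data.frame(structural = 0.5, process = 0.5)
  expect_equal(combine_multi_source(one)$structural, 0.5)
  two <- data.frame(structural = c(0.2, 0.6), process = c(0.4, 0.8))
  expect_equal(combine_multi_source(two), list(structural = 0.4,
                                               process = 0.6))
  expect_error(combine_multi_source(two[0, ]), "at least one")

  fx <- linking_fixture()
  eps <- dplyr::bind_rows(
    mk_ep("E1", area = "sick_child", stated = "F1"),
    mk_ep("E1", area = "sick_child", category = "unskilled"),
    mk_ep("E2", area = "sick_child", stated = "F1"),
    mk_ep("E2", area = "sick_child", category = "public:referral",
          stated = "F4")
  )
  r <- mk_region(fx$facs, fx$cls, eps)
  l <- link_episodes(r, "exact", "sick_child")
  e1 <- l[l$episode_id == "E1", ]
  expect_equal(e1$structural, 0.2)  # pharmacy source excluded from average
  expect_true(e1$skilled_care)
  e2 <- l[l$episode_id == "E2", ]
  expect_equal(e2$structural, mean(c(0.2, 0.7)))
  expect_equal(e2$linked_facilities, "F1;F4")
})

test_that("linking against a sample equal to the census reproduces census links", {
  r <- generate_region(tiny_config(seed = 9))
  for (m in c("euclidean", "admin")) {
    for (area in c("sick_child", "delivery")) {
      ref <- link_episodes(r, m, area)
      same <- link_episodes(r, m, area, facilities = r$facilities)
      expect_identical(ref, same)
    }
  }
})
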