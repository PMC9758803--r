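# Shared vocabulary for the data model. A provider category is the cross of
# managing authority and level of care, written "authority:level"; it is the
# restriction key for all linking. Episode sources may also carry the special
# tags "unskilled" (pharmacy / community health worker) and "none" (no care
# sought).

region_authorities <- function() c("public", "private", "religious", "ngo")
region_levels <- function() c("first_level", "referral")
service_areas <- function() c("sick_child", "delivery")

facility_categories <- function() {
  as.vector(outer(region_authorities(), region_levels(), paste, sep = ":"))
}

source_categories <- function() c(facility_categories(), "unskilled", "none")

make_category <- function(authority, level) paste(authority, level, sep = ":")

score_col <- function(indicator, service_area) {
  paste(indicator, service_area, sep = "_")
}

caseload_col <- function(service_area) paste0("caseload_", service_area)

# Deterministic sub-stream seeds: mixes a master seed with integer keys so a
# single sample draw (or quality simulation) is reproducible in isolation.
# Result is always a valid 32-bit seed.
derive_seed <- function(master, ...) {
  keys <- c(...)
  x <- abs(as.double(master)) %% 2147483647
  for (k in keys) {
    x <- (x * 69069 + abs(as.double(k)) * 30103 + 7) %% 2147483647
  }
  as.integer(x) + 1L
}
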