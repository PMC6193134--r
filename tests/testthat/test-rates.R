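rates_fixture <- function() {
  # 10 consultations, 7 with at least one prescription
  records <- make_records(c(
    as.list(rep("metronidazole 400mg", 5)),
    list(c("meloxicam 10ml", "1x dog annual booster")),
    list("rabbit vhd booster"),
    as.list(rep("consult fee", 3))
  ), species = c(rep("dog", 8), "cat", "cat"))
  events <- map_consultations(records, tiny_rules(), tiny_taxonomy())
  list(records = records, events = events)
}

test_that("consultation-level prescription frequency counts correctly", {
  fx <- rates_fixture()
  expect_equal(consult_prescription_frequency(fx$records, fx$events), 0.7)
  # all prescription-free
  empty <- make_records(as.list(rep("consult fee", 4)))
  ev0 <- map_consultations(empty, tiny_rules(), tiny_taxonomy())
  expect_equal(consult_prescription_frequency(empty, ev0), 0)
  # empty stratum signals undefined, not zero
  expect_error(consult_prescription_frequency(fx$records, fx$events,
                                              species = "ferret"),
               class = "pharmsurv_undefined_result")
})

test_that("rate per 10,000 consultations is the scaled at-least-one count", {
  fx <- rates_fixture()
  # arithmetic oracle: 2 of 10 consultations carry a vaccine event
  expect_equal(rate_per_10k(fx$records, fx$events, "vaccine"),
               10000 * 2 / 10)
  expect_equal(rate_per_10k(fx$records, fx$events, "endectocide"), 0)
  expect_equal(rate_per_10k(fx$records, fx$events, "antibiotic",
                            species = "dog"),
               10000 * 5 / 8)
  # a family in every consultation hits the ceiling
  all_rx <- make_records(as.list(rep("metronidazole 400mg", 3)))
  ev <- map_consultations(all_rx, tiny_rules(), tiny_taxonomy())
  expect_equal(rate_per_10k(all_rx, ev, "antibiotic"), 10000)
})

test_that("animal-level exposure is a fraction of distinct animals", {
  records <- make_records(
    list("metronidazole 400mg", "consult fee", "consult fee"),
    animal_id = c("A1", "A2", "A3"))
  ev <- map_consultations(records, tiny_rules(), tiny_taxonomy())
  expect_equal(animal_level_exposure(records, ev, "dog"), 1 / 3)
  expect_error(animal_level_exposure(records, ev, "hamster"),
               class = "pharmsurv_validation_error")
  # every animal prescribed
  rec2 <- make_records(list("metronidazole 400mg", "meloxicam oral"),
                       animal_id = c("A1", "A2"))
  ev2 <- map_consultations(rec2, tiny_rules(), tiny_taxonomy())
  expect_equal(animal_level_exposure(rec2, ev2, "dog"), 1)
})

test_that("cluster bootstrap degenerates correctly and hits known bounds", {
  # all clusters identical: zero-width interval at the statistic
  d <- data.frame(site = rep(c("s1", "s2", "s3"), each = 4),
                  y = rep(c(0, 1), 6))
  est <- cluster_bootstrap(d, function(x) mean(x$y), "site", n_boot = 200,
                           seed = 1)
  expect_equal(est$ci_low, 0.5)
  expect_equal(est$ci_high, 0.5)
  # single cluster: degenerate with warning
  expect_warning(
    one <- cluster_bootstrap(d[d$site == "s1", ], function(x) mean(x$y),
                             "site", n_boot = 50, seed = 1),
    "one cluster")
  expect_equal(one$ci_low, one$ci_high)
  # two clusters at proportions 0 and 1: the four equally likely resamples
  # give replicate distribution {0, 1/2, 1/2, 1} so the CI spans [0, 1]
  d2 <- data.frame(site = rep(c("a", "b"), each = 10), y = rep(c(0, 1),
                                                               each = 10))
  est2 <- suppressWarnings(
    cluster_bootstrap(d2, function(x) mean(x$y), "site", n_boot = 4000,
                      seed = 2))
  expect_equal(est2$ci_low, 0)
  expect_equal(est2$ci_high, 1)
  expect_error(cluster_bootstrap(d, function(x) mean(x$y), "site",
                                 n_boot = 0),
               class = "pharmsurv_validation_error")
})

test_that("bootstrap interval width shrinks with more independent clusters", {
  width_at <- function(g, seed) {
    set.seed(seed)
    p <- rbeta(g, 8, 4)
    d <- data.frame(site = rep(seq_len(g), each = 20),
                    y = rbinom(g * 20, 1, rep(p, each = 20)))
    est <- suppressWarnings(cluster_bootstrap(d, function(x) mean(x$y),
                                              "site", n_boot = 300,
                                              seed = seed))
    est$ci_high - est$ci_low
  }
  # compare averaged widths over a few seeds to damp Monte-Carlo noise
  w_small <- mean(vapply(1:5, function(s) width_at(8, s), numeric(1)))
  w_large <- mean(vapply(1:5, function(s) width_at(64, s), numeric(1)))
  expect_lt(w_large, w_small)
})

test_that("authorisation breakdown normalises over resolvable events", {
  ev <- tibble::tibble(
    consultation_id = sprintf("C%02d", 1:12),
    species = "dog",
    authorisation = c(rep("veterinary", 9), "human", NA, NA)
  )
  out <- authorisation_breakdown(ev)
  expect_equal(out$proportion[out$authorisation == "veterinary"], 0.9)
  expect_equal(out$proportion[out$authorisation == "human"], 0.1)
  expect_equal(out$proportion[out$authorisation == "generic"], 0)
  expect_equal(sum(out$proportion), 1)
  expect_equal(attr(out, "not_estimable_n"), 2L)
  # all veterinary
  allv <- authorisation_breakdown(
    tibble::tibble(species = "cat", authorisation = rep("veterinary", 5)))
  expect_equal(allv$proportion, c(1, 0, 0))
})

test_that("family rates never exceed the overall prescription frequency", {
  cfg <- synth_config(n_practices = 6, n_animals = 400, seed = 21)
  sim <- generate_dataset(cfg)
  ev <- map_consultations(sim$records, cfg$rules, cfg$taxonomy)
  overall <- consult_prescription_frequency(sim$records, ev)
  for (fam in unique(ev$pf)) {
    expect_lte(rate_per_10k(sim$records, ev, fam) / 10000, overall)
  }
})
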