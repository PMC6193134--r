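test_that("PD matches the published worked example and edge cases", {
  expect_equal(report_round(compute_pd(c(800, 400, 400, 400))), 0.72)
  expect_equal(compute_pd(c(10)), 0)        # single class
  expect_equal(compute_pd(c(7, 0, 0)), 0)   # zero-count classes ignored
  expect_equal(compute_pd(c(1, 1)), 1)      # two singleton classes
  expect_true(is.na(compute_pd(c(1))))      # NP < 2: undefined
  expect_true(is.na(compute_pd(c(0, 0))))
  expect_error(compute_pd(c(-1, 2)), class = "pharmsurv_validation_error")
})

test_that("PD equals the discordant-pair enumeration oracle", {
  expect_equal(compute_pd(c(5, 3, 2)), oracle_pd(c(5, 3, 2)))
  set.seed(42)
  for (rep in 1:40) {
    k <- sample(1:5, 1)
    counts <- as.vector(stats::rmultinom(1, sample(2:30, 1), runif(k) + 0.1))
    expect_equal(compute_pd(counts), oracle_pd(counts),
                 info = paste(counts, collapse = ","))
  }
})

test_that("PD is permutation invariant and responds to merging/splitting", {
  set.seed(7)
  for (rep in 1:20) {
    counts <- sample(0:8, sample(2:6, 1), replace = TRUE)
    if (sum(counts) < 2) next
    expect_equal(compute_pd(counts), compute_pd(rev(counts)))
    expect_equal(compute_pd(counts), compute_pd(sample(counts)))
    # merging two classes never increases PD
    if (length(counts) >= 2) {
      merged <- c(counts[1] + counts[2], counts[-(1:2)])
      expect_lte(compute_pd(merged), compute_pd(counts) + 1e-12)
    }
    # splitting a class evenly never decreases PD
    even <- counts[counts %% 2 == 0 & counts > 0]
    if (length(even) > 0) {
      i <- which(counts == even[1])[1]
      split <- c(counts[-i], counts[i] / 2, counts[i] / 2)
      expect_gte(compute_pd(split), compute_pd(counts) - 1e-12)
    }
  }
})

test_that("even-prescription limits reproduce the published ceilings", {
  expect_equal(report_round(pd_even(4, 2000)), 0.75)
  expect_equal(report_round(pd_even(8, 2000)), 0.88)
  expect_equal(pd_even(1, 100), 0)
  expect_error(pd_even(3, 100), class = "pharmsurv_validation_error")
  # increasing in k at fixed NP; in NP the ceiling equals
  # 1 - (NP - k)/(k (NP - 1)), which approaches 1 - 1/k from above
  ks <- c(2, 4, 5, 8, 10)
  vals <- vapply(ks, pd_even, numeric(1), np_total = 2000)
  expect_true(all(diff(vals) > 0))
  nps <- c(16, 160, 1600, 16000)
  vals_np <- vapply(nps, function(np) pd_even(8, np), numeric(1))
  expect_true(all(diff(vals_np) < 0))
  expect_true(all(vals_np > 1 - 1 / 8))
  expect_lt(abs(pd_even(8, 80000) - (1 - 1 / 8)), 1e-4)
})

test_that("practice PD table computes per practice and flags undefined", {
  tax <- tiny_taxonomy()
  # practice A: aminopenicillin 800, fluoroquinolone 400, nitroimidazole 400,
  # quinoline-free fourth class approximated by amox split
  events <- tibble::tibble(
    consultation_id = sprintf("C%04d", 1:2011),
    animal_id = "A1", species = "dog",
    practice_id = c(rep("P1", 2000), rep("P2", 10), "P3"),
    site_id = "S1", date = as.Date("2015-06-01"), mpc = "other unwell",
    agent = "x",
    pc = c(rep(c("pc1", "pc2", "pc3", "pc4"), c(800, 400, 400, 400)),
           rep("pc1", 10), "pc1"),
    pf = "antibiotic",
    authorisation = "veterinary",
    n_descriptions = 1L
  )
  tb <- practice_pd_table(events, "antibiotic")
  expect_equal(report_round(tb$pd[tb$practice_id == "P1"]), 0.72)
  expect_equal(tb$pd[tb$practice_id == "P2"], 0)
  expect_true(is.na(tb$pd[tb$practice_id == "P3"])) # one prescription
  # family-only (unresolved class) events are excluded from PD
  events$pc[1:100] <- NA
  tb2 <- practice_pd_table(events, "antibiotic")
  expect_equal(tb2$np_total[tb2$practice_id == "P1"], 1900L)
  # a family with no class-resolved events: empty table with warning
  events_nopc <- events
  events_nopc$pc <- NA
  expect_warning(tb3 <- practice_pd_table(events_nopc, "antibiotic"))
  expect_equal(nrow(tb3), 0)
})

test_that("quintile benchmarking matrix reflects rank concordance", {
  ids <- sprintf("P%02d", 1:10)
  freq <- tibble::tibble(practice_id = ids, value = 1:10)
  concordant <- benchmark_quintile_matrix(
    freq, tibble::tibble(practice_id = ids, value = (1:10) * 2))
  expect_equal(unname(diag(concordant)), rep(2L, 5))
  expect_equal(sum(concordant), 10L)
  reversed <- benchmark_quintile_matrix(
    freq, tibble::tibble(practice_id = ids, value = 10:1))
  expect_equal(concordant[, 5:1], reversed, ignore_attr = TRUE)
  expect_error(
    benchmark_quintile_matrix(freq[1:4, ],
                              tibble::tibble(practice_id = ids[1:4],
                                             value = 1:4)),
    class = "pharmsurv_validation_error")
})

test_that("uneven practice counts fill earlier quintiles first", {
  ids <- sprintf("P%02d", 1:12)
  m <- benchmark_quintile_matrix(
    tibble::tibble(practice_id = ids, value = 1:12),
    tibble::tibble(practice_id = ids, value = 1:12))
  expect_equal(unname(rowSums(m)), c(3L, 3L, 2L, 2L, 2L))
  expect_equal(sum(m), 12L)
})

test_that("independent metrics spread practices across the matrix", {
  set.seed(3)
  ids <- sprintf("P%03d", 1:216)
  m <- benchmark_quintile_matrix(
    tibble::tibble(practice_id = ids, value = runif(216)),
    tibble::tibble(practice_id = ids, value = runif(216)))
  expect_equal(sum(m), 216L)
  # cell expectation 216/25 = 8.64; allow generous multinomial noise
  expect_true(all(m >= 1) && all(m <= 20))
})
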