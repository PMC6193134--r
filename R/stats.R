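#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' Tests every unordered pair of groups (typically practice-level PD values
#' per species) with the two-sample Wilcoxon rank-sum test and adjusts the
#' p-values by Bonferroni (multiplied by the number of pairs, capped at 1).
#' Small tie-free samples use the exact null distribution; larger or tied
#' samples use the normal approximation with tie correction — practice-level
#' PD contains many exact zeros, so ties are the norm, not the exception.
#' Undefined (`NA`) values are dropped per group before testing.
#'
#' @param values Numeric vector of observations.
#' @param groups Vector of group labels, same length.
#' @return Tibble (`group_a`, `group_b`, `statistic`, `raw_p`, `adj_p`),
#'   one row per pair.
#' @export
pairwise_wilcoxon <- function(values, groups) {
  groups <- as.character(groups)
  keep <- !is.na(values)
  values <- values[keep]; groups <- groups[keep]
  lvls <- unique(groups)
  if (length(lvls) < 2) {
    abort("at least two groups with defined values are required",
          class = "pharmsurv_validation_error")
  }
  pairs <- utils::combn(lvls, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- values[groups == pairs[1, i]]
    b <- values[groups == pairs[2, i]]
    wt <- suppressWarnings(wilcox.test(a, b))
    tibble::tibble(group_a = pairs[1, i], group_b = pairs[2, i],
                   statistic = unname(wt$statistic), raw_p = wt$p.value)
  })
  out <- dplyr::bind_rows(res)
  out$adj_p <- pmin(1, out$raw_p * nrow(out))
  out
}

#' Kendall rank correlation with t-approximation p-value
#'
#' Tie-corrected Kendall tau (tau-b) between two paired practice-level
#' metrics, with a p-value from the t approximation
#' `t = tau * sqrt(n - 2) / sqrt(1 - tau^2)` on `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric vectors; pairs with an `NA` in either are
#'   dropped.
#' @return A list of class `correlation_result`: `tau`, `statistic` (the t
#'   value), `p`, `n`.
#' @export
#' @examples
#' kendall_correlation(1:5, c(1, 3, 2, 5, 4)) # tau 0.6
kendall_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    abort("at least 3 complete pairs are required",
          class = "pharmsurv_validation_error")
  }
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("correlation undefined for a constant metric",
          class = "pharmsurv_undefined_result")
  }
  tau <- cor(x, y, method = "kendall")
  if (abs(tau) >= 1) {
    tstat <- sign(tau) * Inf
    p <- 0
  } else {
    tstat <- tau * sqrt(n - 2) / sqrt(1 - tau^2)
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(tau = tau, statistic = tstat, p = p, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Kendall tau = %.3f (t = %.2f, P = %.3g, n = %d)\n",
              x$tau, x$statistic, x$p, x$n))
  invisible(x)
}

#' Run the full surveillance pipeline on synthetic data
#'
#' Orchestrates the whole analysis end to end: generate (or accept)
#' consultation records, map free text to prescription events, estimate
#' frequencies, compute per-practice Prescription Diversity and the
#' benchmarking quintile matrix, build/sparsify the co-prescription network
#' with group detection, and run the comparative statistics. Deterministic
#' under fixed seeds.
#'
#' @param config A [synth_config()] (used when `records` is `NULL`).
#' @param records Optional pre-existing consultation records.
#' @param seed Integer seed for generation, bootstrap and group detection.
#' @param n_boot Bootstrap replicates for the frequency interval (kept small
#'   by default for interactive use; the reference analysis uses 5000).
#' @param pd_family Family used for the diversity and benchmarking stages.
#' @param out_dir Optional directory; when given, stage CSVs, network
#'   exports and a JSON summary are written there.
#' @return A list: `events`, `mapping`, `frequency` (rate_estimate),
#'   `rates_by_species`, `authorisation`, `pd_table`, `pd_medians`,
#'   `benchmark`, `network`, `groups`, `coprescription_rate`, `wilcoxon`,
#'   `kendall`, `summary` (the JSON-ready summary list).
#' @export
run_pipeline <- function(config = synth_config(), records = NULL,
                         seed = 1L, n_boot = 200, pd_family = "antibiotic",
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "pharmsurv_pipeline_error")
    })
  }
  truth <- NULL
  if (is.null(records)) {
    sim <- stage("simulate", generate_dataset(config, seed = seed))
    records <- sim$records
    truth <- sim$truth
  }
  rules <- config$rules
  taxonomy <- config$taxonomy

  events <- stage("map", map_consultations(records, rules, taxonomy))
  mapping <- mapping_summary(events)

  frequency <- stage("rates", prescription_frequency_ci(
    records, events, n_boot = n_boot, seed = seed))
  species_present <- sort(unique(records$species))
  rates_by_species <- stage("rates", dplyr::bind_rows(lapply(
    species_present, function(sp) {
      tibble::tibble(
        species = sp,
        frequency = consult_prescription_frequency(records, events,
                                                   species = sp),
        animal_exposure = animal_level_exposure(records, events, sp)
      )
    })))
  authorisation <- stage("rates", authorisation_breakdown(events))

  pd_table <- stage("diversity", dplyr::bind_rows(lapply(
    species_present, function(sp) {
      tb <- practice_pd_table(events, pd_family, species = sp)
      if (nrow(tb) > 0) tb$species <- sp
      tb
    })))
  pd_medians <- stage("diversity", dplyr::summarise(
    dplyr::group_by(pd_table, .data$species),
    median_pd = median(.data$pd, na.rm = TRUE),
    n_practices = sum(!is.na(.data$pd)), .groups = "drop"))

  pd_all <- stage("diversity", practice_pd_table(events, pd_family))
  freq_by_practice <- stage("diversity", {
    consults <- consult_table(records)
    fam_ev <- events[events$pf == pd_family, , drop = FALSE]
    per <- dplyr::summarise(
      dplyr::group_by(consults, .data$practice_id),
      value = mean(.data$consultation_id %in% fam_ev$consultation_id),
      .groups = "drop")
    per
  })
  benchmark <- stage("diversity", {
    pd_metric <- tibble::tibble(practice_id = pd_all$practice_id,
                                value = pd_all$pd)
    benchmark_quintile_matrix(freq_by_practice, pd_metric)
  })

  sets <- stage("network", consult_pf_sets(events))
  network <- stage("network", detect_groups(sparsify(build_network(sets)),
                                            seed = seed))
  corate <- stage("network", coprescription_rate(sets))

  wilcoxon <- stage("stats", {
    ok <- pd_table[!is.na(pd_table$pd), , drop = FALSE]
    if (length(unique(ok$species)) >= 2) pairwise_wilcoxon(ok$pd, ok$species)
    else NULL
  })
  kendall <- stage("stats", {
    consults <- consult_table(records)
    n_consults <- dplyr::count(consults, .data$practice_id,
                               name = "n_consults")
    joined <- dplyr::inner_join(pd_all, n_consults, by = "practice_id")
    joined <- joined[!is.na(joined$pd), , drop = FALSE]
    if (nrow(joined) >= 3 && length(unique(joined$pd)) > 1)
      kendall_correlation(joined$pd, joined$n_consults)
    else NULL
  })

  summary <- list(
    seed = seed,
    n_consultations = nrow(consult_table(records)),
    n_events = nrow(events),
    mapping = as.list(mapping),
    prescription_frequency = list(statistic = frequency$statistic,
                                  ci_low = frequency$ci_low,
                                  ci_high = frequency$ci_high,
                                  cluster_level = frequency$cluster_level),
    rates_by_species = rates_by_species,
    authorisation = authorisation,
    pd_family = pd_family,
    pd_medians = pd_medians,
    benchmark = benchmark,
    coprescription_rate = corate,
    groups = network$groups,
    wilcoxon = wilcoxon,
    kendall = if (!is.null(kendall)) list(tau = kendall$tau, p = kendall$p)
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
    write.csv(pd_table, file.path(out_dir, "pd.csv"), row.names = FALSE)
    write.csv(rates_by_species, file.path(out_dir, "rates.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(benchmark), file.path(out_dir, "benchmark.csv"),
              row.names = FALSE)
    write_network(network, out_dir)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", matrix = "rowmajor",
                         force = TRUE)
  }

  list(events = events, mapping = mapping, frequency = frequency,
       rates_by_species = rates_by_species, authorisation = authorisation,
       pd_table = pd_table, pd_medians = pd_medians, benchmark = benchmark,
       network = network, groups = network$groups,
       coprescription_rate = corate, wilcoxon = wilcoxon, kendall = kendall,
       truth = truth, summary = summary)
}
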