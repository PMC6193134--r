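# consultation-level view of a records table (one row per consultation)
consult_table <- function(records) {
  dplyr::distinct(records[setdiff(required_record_cols(), "description")])
}

filter_events <- function(events, species = NULL, pf = NULL,
                          authorisation = NULL) {
  if (!is.null(species)) events <- events[events$species %in% species, ]
  if (!is.null(pf)) events <- events[events$pf %in% pf, ]
  if (!is.null(authorisation)) {
    events <- events[!is.na(events$authorisation) &
                       events$authorisation %in% authorisation, ]
  }
  events
}

#' Proportion of consultations with at least one prescription
#'
#' Fraction of booked consultations (repeat visits counted separately) where
#' at least one qualifying prescription event was recorded, optionally
#' restricted by species, family and/or authorisation category.
#'
#' @param records Consultation records (one row per description).
#' @param events Prescription events from [map_consultations()].
#' @param species,pf,authorisation Optional filters.
#' @return A proportion in \[0, 1\].
#' @export
consult_prescription_frequency <- function(records, events, species = NULL,
                                           pf = NULL, authorisation = NULL) {
  consults <- consult_table(records)
  if (!is.null(species)) consults <- consults[consults$species %in% species, ]
  if (nrow(consults) == 0) {
    abort("no consultations in the requested stratum; proportion undefined",
          class = "pharmsurv_undefined_result")
  }
  ev <- filter_events(events, species = species, pf = pf,
                      authorisation = authorisation)
  mean(consults$consultation_id %in% ev$consultation_id)
}

#' Prescription rate per 10,000 consultations
#'
#' `10000 x (consultations with >= 1 event of the family) / (consultations
#' in the stratum)`.
#'
#' @inheritParams consult_prescription_frequency
#' @param pf Pharmaceutical family of interest.
#' @return Rate per 10,000 consultations.
#' @export
#' @examples
#' # 558 of 2000 consultations with a vaccine -> 2790 per 10,000
rate_per_10k <- function(records, events, pf, species = NULL) {
  10000 * consult_prescription_frequency(records, events, species = species,
                                         pf = pf)
}

#' Animal-level exposure proportion
#'
#' Fraction of distinct animals of a species with at least one prescription
#' event over the whole observation window.
#'
#' @inheritParams consult_prescription_frequency
#' @param species Species label; must occur in the records.
#' @return A proportion in \[0, 1\].
#' @export
animal_level_exposure <- function(records, events, species) {
  consults <- consult_table(records)
  if (!species %in% consults$species) {
    abort(paste0("unknown species label: ", species),
          class = "pharmsurv_validation_error")
  }
  animals <- unique(consults$animal_id[consults$species == species])
  exposed <- unique(events$animal_id[events$species == species])
  mean(animals %in% exposed)
}

#' Cluster-bootstrap confidence interval for a statistic
#'
#' Resamples whole clusters with replacement (the same number of clusters as
#' observed, within strata when given), recomputes the statistic on each
#' replicate, and returns percentile bounds. Resampling intact clusters
#' keeps within-cluster correlation in every replicate, which is what makes
#' the interval valid for clustered observations (animals within practices,
#' consultations within sites).
#'
#' @param data Data frame of records (rows are the resampling units'
#'   members).
#' @param stat_fn Function `data.frame -> number`, the statistic.
#' @param cluster Name of the column identifying clusters.
#' @param strata Optional column name; clusters are resampled independently
#'   within each stratum (e.g. animals within practices).
#' @param n_boot Number of bootstrap replicates (the reference analysis uses
#'   5000).
#' @param conf Confidence level for the percentile interval.
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `rate_estimate`: `statistic` (on the observed
#'   data), `ci_low`, `ci_high`, `n_boot`, `n_clusters`, `cluster_level`.
#'   If the observed statistic falls outside the percentile interval (rare,
#'   a known quirk of the percentile method) the interval is clamped to
#'   include it and a warning is raised; a single cluster yields a
#'   degenerate zero-width interval with a warning.
#' @export
cluster_bootstrap <- function(data, stat_fn, cluster, strata = NULL,
                              n_boot = 5000, conf = 0.95, seed = NULL) {
  if (n_boot < 1) {
    abort("n_boot must be >= 1", class = "pharmsurv_validation_error")
  }
  if (!cluster %in% names(data)) {
    abort(paste0("cluster column '", cluster, "' not found"),
          class = "pharmsurv_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  data <- as.data.frame(data)
  observed <- stat_fn(data)

  strat <- if (is.null(strata)) rep("all", nrow(data)) else data[[strata]]
  key <- paste(strat, data[[cluster]], sep = "\r")
  idx_by_cluster <- split(seq_len(nrow(data)), key)
  cluster_stratum <- sub("\r.*$", "", names(idx_by_cluster))
  clusters_in_stratum <- split(seq_along(idx_by_cluster), cluster_stratum)
  n_clusters <- length(idx_by_cluster)
  if (n_clusters == 1) {
    warn("only one cluster: bootstrap interval is degenerate (width 0)")
    return(structure(list(statistic = observed, ci_low = observed,
                          ci_high = observed, n_boot = as.integer(n_boot),
                          n_clusters = 1L, cluster_level = cluster),
                     class = "rate_estimate"))
  }

  reps <- vapply(seq_len(n_boot), function(b) {
    chosen <- unlist(lapply(clusters_in_stratum, function(cl) {
      cl[sample.int(length(cl), length(cl), replace = TRUE)]
    }), use.names = FALSE)
    stat_fn(data[unlist(idx_by_cluster[chosen], use.names = FALSE), ,
                 drop = FALSE])
  }, numeric(1))

  alpha <- (1 - conf) / 2
  ci <- unname(quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE))
  if (observed < ci[1] || observed > ci[2]) {
    warn("observed statistic outside percentile interval; clamping bounds")
    ci[1] <- min(ci[1], observed)
    ci[2] <- max(ci[2], observed)
  }
  structure(list(statistic = observed, ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot), n_clusters = n_clusters,
                 cluster_level = if (is.null(strata)) cluster else
                   paste0(cluster, " within ", strata)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%.4f (95%% CI %.4f-%.4f; %d bootstrap replicates over %d %s clusters)\n",
              x$statistic, x$ci_low, x$ci_high, x$n_boot, x$n_clusters,
              x$cluster_level))
  invisible(x)
}

#' Prescription frequency with a clustering-adjusted interval
#'
#' Convenience wrapper producing the consultation-level prescription
#' frequency with two one-stage cluster bootstraps — clusters = sites, and
#' clusters = animals stratified by practice — and reporting the wider of
#' the two intervals. Running both levels separately and keeping the more
#' conservative interval is transparent about which level of clustering
#' dominates.
#'
#' @inheritParams consult_prescription_frequency
#' @param n_boot Bootstrap replicates per scheme.
#' @param seed Integer seed.
#' @return A `rate_estimate` whose `cluster_level` names the scheme that
#'   produced the wider interval.
#' @export
prescription_frequency_ci <- function(records, events, species = NULL,
                                      pf = NULL, n_boot = 5000, seed = NULL) {
  consults <- consult_table(records)
  if (!is.null(species)) consults <- consults[consults$species %in% species, ]
  ev <- filter_events(events, species = species, pf = pf)
  consults$has_rx <- consults$consultation_id %in% ev$consultation_id
  stat_fn <- function(d) mean(d$has_rx)
  by_site <- cluster_bootstrap(consults, stat_fn, cluster = "site_id",
                               n_boot = n_boot, seed = seed)
  by_animal <- cluster_bootstrap(consults, stat_fn, cluster = "animal_id",
                                 strata = "practice_id", n_boot = n_boot,
                                 seed = seed)
  wider <- if ((by_site$ci_high - by_site$ci_low) >=
               (by_animal$ci_high - by_animal$ci_low)) by_site else by_animal
  wider
}

#' Authorisation category breakdown of prescription events
#'
#' Proportions of prescription events by authorisation category
#' (veterinary, human, generic) over the events whose agent could be
#' resolved. Family-level events with unresolved agents have no defined
#' authorisation and are reported separately (attribute
#' `"not_estimable_n"`), mirroring how such rows are footnoted rather than
#' folded into the denominator.
#'
#' @param events Prescription events.
#' @param species Optional species filter.
#' @return Tibble (`authorisation`, `n`, `proportion`) whose proportions sum
#'   to 1 over defined events; attributes `not_estimable_n` and
#'   `not_estimable_fraction` describe the unresolved remainder.
#' @export
authorisation_breakdown <- function(events, species = NULL) {
  if (!is.null(species)) events <- events[events$species %in% species, ]
  defined <- events[!is.na(events$authorisation), , drop = FALSE]
  counts <- table(factor(defined$authorisation, levels = auth_levels()))
  out <- tibble::tibble(
    authorisation = auth_levels(),
    n = as.integer(counts),
    proportion = if (nrow(defined) > 0) as.integer(counts) / nrow(defined)
                 else rep(NA_real_, 3)
  )
  attr(out, "not_estimable_n") <- nrow(events) - nrow(defined)
  attr(out, "not_estimable_fraction") <-
    if (nrow(events) > 0) (nrow(events) - nrow(defined)) / nrow(events)
    else NA_real_
  out
}
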