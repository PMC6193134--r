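#' Prescription Diversity of one pharmaceutical family at one practice
#'
#' Prescription Diversity (PD) adapts the Simpson diversity index to
#' prescribing: given per-class prescription counts \eqn{np} within one
#' pharmaceutical family (total \eqn{NP}),
#' \deqn{PD = 1 - \frac{\sum np(np-1)}{NP(NP-1)}}
#' which is the probability that two prescriptions drawn without replacement
#' from the family belong to different pharmaceutical classes. PD is 0 when
#' a single class accounts for everything and approaches \eqn{1 - 1/k} when
#' \eqn{k} classes are prescribed evenly.
#'
#' @param np_counts Non-negative integer vector of per-class prescription
#'   counts within one family for one practice.
#' @return PD in \[0, 1\], or `NA` when fewer than two prescriptions were
#'   made (the statistic is undefined for `NP < 2`).
#' @export
#' @examples
#' compute_pd(c(800, 400, 400, 400)) # 0.72 at 2 d.p.
compute_pd <- function(np_counts) {
  if (!is.numeric(np_counts) || length(np_counts) == 0) {
    abort("np_counts must be a numeric vector of class counts",
          class = "pharmsurv_validation_error")
  }
  if (any(is.na(np_counts)) || any(np_counts < 0) ||
      any(np_counts != floor(np_counts))) {
    abort("np_counts must be non-negative integers",
          class = "pharmsurv_validation_error")
  }
  np_total <- sum(np_counts)
  if (np_total < 2) return(NA_real_)
  1 - sum(np_counts * (np_counts - 1)) / (np_total * (np_total - 1))
}

#' Natural PD limit of an evenly prescribed family
#'
#' The PD attained by a "completely diverse" family in which all `k`
#' available classes are prescribed equally often. Because this ceiling
#' depends on `k`, PD should only be compared within a family, never across
#' families.
#'
#' @param k Number of pharmaceutical classes (>= 1).
#' @param np_total Total prescriptions, divisible by `k` and >= 2.
#' @return The PD of `k` equal counts of `np_total / k`.
#' @export
#' @examples
#' pd_even(4, 2000) # 0.75 at 2 d.p.
#' pd_even(8, 2000) # 0.88 at 2 d.p.
pd_even <- function(k, np_total) {
  if (k < 1 || k != floor(k)) {
    abort("k must be a positive integer", class = "pharmsurv_validation_error")
  }
  if (np_total < 2 || np_total %% k != 0) {
    abort("np_total must be >= 2 and divisible by k",
          class = "pharmsurv_validation_error")
  }
  compute_pd(rep(np_total / k, k))
}

#' Per-practice PD table for one pharmaceutical family
#'
#' Computes PD for every practice with at least one class-resolved event of
#' the family, optionally restricted to a species and/or main presenting
#' complaint. Family-level events whose class could not be resolved (e.g.
#' generic vaccine descriptors) are excluded: PD is defined over classes
#' within a family. Practices with a single prescription have undefined PD
#' (`NA`); they are kept in the table but should be dropped before medians
#' or ranking.
#'
#' @param events Prescription events from [map_consultations()].
#' @param pf Pharmaceutical family label.
#' @param species Optional species filter.
#' @param mpc Optional main-presenting-complaint filter.
#' @return Tibble with columns `practice_id`, `pf`, `pd`, `np_total`,
#'   `n_classes_prescribed`.
#' @export
practice_pd_table <- function(events, pf, species = NULL, mpc = NULL) {
  sel <- events[events$pf == pf & !is.na(events$pc), , drop = FALSE]
  if (!is.null(species)) sel <- sel[sel$species %in% species, , drop = FALSE]
  if (!is.null(mpc)) sel <- sel[sel$mpc %in% mpc, , drop = FALSE]
  if (nrow(sel) == 0) {
    warn(paste0("no class-resolved events for family '", pf, "'"))
    return(tibble::tibble(practice_id = character(), pf = character(),
                          pd = double(), np_total = integer(),
                          n_classes_prescribed = integer()))
  }
  counts <- dplyr::count(sel, .data$practice_id, .data$pc)
  out <- dplyr::summarise(
    dplyr::group_by(counts, .data$practice_id),
    pd = compute_pd(.data$n),
    np_total = sum(.data$n),
    n_classes_prescribed = dplyr::n_distinct(.data$pc),
    .groups = "drop"
  )
  out$pf <- pf
  out[c("practice_id", "pf", "pd", "np_total", "n_classes_prescribed")]
}

#' Practice benchmarking matrix of frequency vs diversity quintiles
#'
#' Ranks practices separately by prescription frequency and by PD, splits
#' each ranking into five (near-)equal quintiles, and cross-tabulates the
#' two memberships. Cell (i, j) counts practices in frequency quintile i and
#' PD quintile j, with quintile 1 the lowest. Ties are broken by a stable
#' sort on practice id; when the practice count is not divisible by five the
#' earlier quintiles receive the extra members.
#'
#' @param freq Tibble (`practice_id`, `value`) of per-practice prescription
#'   frequencies, or a named numeric vector.
#' @param pd Same shape, per-practice PD. Practices must match `freq`;
#'   practices with undefined (`NA`) values in either metric are dropped.
#' @return A 5 x 5 integer matrix (rows = frequency quintile, columns = PD
#'   quintile); cell counts sum to the number of ranked practices.
#' @export
benchmark_quintile_matrix <- function(freq, pd) {
  freq <- as_metric_tbl(freq, "freq")
  pd <- as_metric_tbl(pd, "pd")
  both <- dplyr::inner_join(freq, pd, by = "practice_id",
                            suffix = c("_freq", "_pd"))
  both <- both[!is.na(both$value_freq) & !is.na(both$value_pd), , drop = FALSE]
  n <- nrow(both)
  if (n < 5) {
    abort("at least 5 practices with both metrics defined are required",
          class = "pharmsurv_validation_error")
  }
  qf <- quintile_assign(both$value_freq, both$practice_id)
  qp <- quintile_assign(both$value_pd, both$practice_id)
  m <- table(factor(qf, levels = 1:5), factor(qp, levels = 1:5))
  m <- matrix(as.integer(m), nrow = 5,
              dimnames = list(freq_quintile = 1:5, pd_quintile = 1:5))
  m
}

as_metric_tbl <- function(x, what) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- tibble::tibble(practice_id = names(x), value = unname(x))
  }
  if (!all(c("practice_id", "value") %in% names(x))) {
    abort(paste0(what, " must have columns practice_id and value"),
          class = "pharmsurv_validation_error")
  }
  tibble::as_tibble(x[c("practice_id", "value")])
}

# stable rank -> quintile membership; earlier quintiles take the remainder
quintile_assign <- function(values, ids) {
  ord <- order(values, ids)
  n <- length(values)
  sizes <- rep(n %/% 5, 5)
  if (n %% 5 > 0) sizes[seq_len(n %% 5)] <- sizes[seq_len(n %% 5)] + 1
  q <- rep(1:5, sizes)
  out <- integer(n)
  out[ord] <- q
  out
}

#' Round for reporting
#'
#' Half-even rounding to two decimal places, the precision at which PD and
#' related proportions are reported.
#' @param x Numeric vector.
#' @return `x` rounded to 2 decimal places.
#' @export
report_round <- function(x) round(x, 2)
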