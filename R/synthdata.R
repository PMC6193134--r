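#' Configuration for the synthetic EHR generator
#'
#' Builds (and validates) the parameter set for [generate_dataset()]. The
#' generator emulates the structure of a sentinel network of companion-animal
#' practices: practices with one or more sites, animals nested in practices,
#' booked consultations each coded with one of ten main presenting
#' complaints, free-text product descriptions, and three planted
#' co-prescription blocks over pharmaceutical families (preventive care,
#' treatment of disease, euthanasia). Euthanasia consultations never
#' co-prescribe outside their block. Practice-level random effects on
#' prescribing propensity create the within-cluster correlation that the
#' cluster bootstrap is meant to absorb.
#'
#' @param n_practices Number of practices.
#' @param sites_per_practice Integer vector of candidate site counts; each
#'   practice draws one uniformly.
#' @param n_animals Number of animals across the network.
#' @param species_mix Named probabilities over `dog`, `cat`, `rabbit`.
#' @param consult_lambda Consultations per animal are `1 + Poisson(lambda)`.
#' @param mpc_probs Named probabilities over the ten main presenting
#'   complaints.
#' @param preventive_mpcs Complaints whose consultations draw from the
#'   preventive block profile; all others use the treatment profile.
#' @param pf_profiles List with named probability vectors `preventive` and
#'   `treatment` over the pharmaceutical families of each block.
#' @param set_size_probs Probabilities that a prescribing consultation
#'   carries 1, 2 or 3 distinct families from its block.
#' @param euthanasia_rate Fraction of prescribing treatment-block
#'   consultations that are euthanasia-only.
#' @param leak_rate Probability that a non-euthanasia prescribing
#'   consultation additionally carries one family from the other block
#'   (the rare between-block co-prescription).
#' @param prescribe_prob Population-average probability that a consultation
#'   records at least one prescription.
#' @param practice_sd Standard deviation of the practice random effect on
#'   the logit of `prescribe_prob`.
#' @param pc_concentration Dirichlet concentration for per-practice class
#'   mixes within each family (smaller = more between-practice PD spread).
#' @param authorisation_mix Named probabilities over `veterinary`, `human`,
#'   `generic` applied to every class-resolved prescription.
#' @param decoy_rate Probability that a prescribing consultation carries an
#'   additional non-prescription description; non-prescribing consultations
#'   always carry one.
#' @param break_rate Probability that a planted prescription is rendered as
#'   text no rule can match (unrecorded/unrecognisable products).
#' @param seed Integer seed; fully determines the generated dataset.
#' @param taxonomy,rules Taxonomy and rule set used for rendering and for
#'   ground truth; default to the bundled examples.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_practices = 50,
                         sites_per_practice = 1:3,
                         n_animals = 5000,
                         species_mix = c(dog = 0.60, cat = 0.30, rabbit = 0.10),
                         consult_lambda = 7,
                         mpc_probs = c("gastroenteric" = 0.10,
                                       "respiratory" = 0.07,
                                       "pruritus" = 0.10,
                                       "trauma" = 0.07,
                                       "tumour" = 0.05,
                                       "kidney disease" = 0.05,
                                       "other unwell" = 0.08,
                                       "post-operative" = 0.08,
                                       "vaccination" = 0.25,
                                       "other healthy" = 0.15),
                         preventive_mpcs = c("vaccination", "other healthy"),
                         pf_profiles = list(
                           preventive = c("vaccine" = 0.45,
                                          "ectoparasiticide" = 0.20,
                                          "endectocide" = 0.20,
                                          "endoparasiticide" = 0.15),
                           treatment = c("antibiotic" = 0.26,
                                         "anti-inflammatory" = 0.26,
                                         "gastrointestinal" = 0.12,
                                         "neurological" = 0.09,
                                         "antimycotic" = 0.07,
                                         "cardiovascular" = 0.07,
                                         "replacement agent" = 0.07,
                                         "endocrine" = 0.06)),
                         set_size_probs = c(0.55, 0.30, 0.15),
                         euthanasia_rate = 0.04,
                         leak_rate = 0.02,
                         prescribe_prob = 0.65,
                         practice_sd = 0.5,
                         pc_concentration = 6,
                         authorisation_mix = c(veterinary = 0.90,
                                               human = 0.06,
                                               generic = 0.04),
                         decoy_rate = 0.30,
                         break_rate = 0.01,
                         seed = 1L,
                         taxonomy = NULL,
                         rules = NULL) {
  cfg <- list(
    n_practices = n_practices, sites_per_practice = sites_per_practice,
    n_animals = n_animals, species_mix = species_mix,
    consult_lambda = consult_lambda, mpc_probs = mpc_probs,
    preventive_mpcs = preventive_mpcs, pf_profiles = pf_profiles,
    set_size_probs = set_size_probs, euthanasia_rate = euthanasia_rate,
    leak_rate = leak_rate, prescribe_prob = prescribe_prob,
    practice_sd = practice_sd, pc_concentration = pc_concentration,
    authorisation_mix = authorisation_mix, decoy_rate = decoy_rate,
    break_rate = break_rate, seed = as.integer(seed),
    taxonomy = taxonomy %||% example_taxonomy(),
    rules = rules
  )
  if (is.null(cfg$rules)) {
    cfg$rules <- if (is.null(taxonomy)) example_rules() else
      abort("rules must be supplied when a custom taxonomy is used",
            class = "pharmsurv_config_error")
  }
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  check_probs <- function(p, field) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort(paste0("probability vector '", field,
                   "' must be non-negative and sum to 1"),
            class = "pharmsurv_config_error")
    }
  }
  counts <- c(n_practices = cfg$n_practices, n_animals = cfg$n_animals)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("n_practices and n_animals must be non-negative integers",
          class = "pharmsurv_config_error")
  }
  if (cfg$n_practices == 0 && cfg$n_animals > 0) {
    abort("n_practices must be positive when animals are generated",
          class = "pharmsurv_config_error")
  }
  check_probs(cfg$species_mix, "species_mix")
  check_probs(cfg$mpc_probs, "mpc_probs")
  check_probs(cfg$set_size_probs, "set_size_probs")
  check_probs(cfg$authorisation_mix, "authorisation_mix")
  for (b in names(cfg$pf_profiles)) {
    check_probs(cfg$pf_profiles[[b]], paste0("pf_profiles$", b))
  }
  for (r in c("euthanasia_rate", "leak_rate", "prescribe_prob",
              "decoy_rate", "break_rate")) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) {
      abort(paste0("'", r, "' must be a probability in [0, 1]"),
            class = "pharmsurv_config_error")
    }
  }
  bad_pf <- setdiff(unlist(lapply(cfg$pf_profiles, names)), cfg$taxonomy$pf)
  if (length(bad_pf) > 0) {
    abort(paste0("pf_profiles reference families absent from the taxonomy: ",
                 paste(bad_pf, collapse = ", ")),
          class = "pharmsurv_config_error")
  }
  invisible(cfg)
}

# weighted sampling of `m` distinct items per row via the exponential race
# (equivalent to successive sampling without replacement)
sample_distinct_sets <- function(items, prob, m, n) {
  k <- length(items)
  if (n == 0) return(matrix(character(), nrow = 0, ncol = m))
  e <- matrix(stats::rexp(n * k), nrow = n) /
    matrix(prob, nrow = n, ncol = k, byrow = TRUE)
  picks <- t(apply(e, 1, function(row) order(row)[seq_len(m)]))
  if (m == 1) picks <- matrix(picks, ncol = 1)
  matrix(items[picks], nrow = n, ncol = m)
}

#' Render a prescription event as practitioner-style product text
#'
#' Produces the free-text description a practitioner might type for a
#' prescription: the agent's identifying name (occasionally a brand synonym)
#' plus noisy strength/form/quantity decoration and random casing, all of
#' which the normalisation step strips back out. Family-level events use
#' descriptor wording (e.g. annual booster text for vaccines). With
#' `broken = TRUE` the text is an opaque sundry line that no rule matches,
#' emulating unrecorded or unrecognisable products.
#'
#' @param agent Character vector of agent names (`"unresolved"` for
#'   family-level events).
#' @param pf Character vector of pharmaceutical families, same length.
#' @param broken Logical vector: render as unmatchable text.
#' @return Character vector of raw product descriptions.
#' @export
#' @examples
#' set.seed(1)
#' render_description("metronidazole", "antibiotic")
render_description <- function(agent, pf, broken = FALSE) {
  n <- length(agent)
  broken <- rep_len(broken, n)
  strengths <- c("50mg", "100mg", "250mg", "400mg", "20mg/ml", "2.5mg")
  forms <- c(" tablet", " tabs", " susp", " inj", " spot-on", "")
  suffix <- c("", " x1", " x2")
  descriptors <- list(
    "vaccine" = c("1x dog annual booster", "cat flu vaccine",
                  "rabbit vhd vaccine", "puppy vacc second dose",
                  "kennel cough booster"),
    "euthanasia" = c("euthanasia of patient", "pentoject 100ml",
                     "home visit euthanasia", "pentobarbitone injection"),
    "neurological" = c("sedative given", "mild sedative pre-op"),
    "replacement agent" = c("hartmanns 500ml iv", "vitamin b12 injection",
                            "electrolyte sachet")
  )
  broken_pool <- c("sundry item", "misc consumable", "dispensing charge",
                   "out of hours supplement", "clinical waste charge")
  synonyms <- c(meloxicam = "metacam")

  out <- character(n)
  is_unres <- agent == "unresolved" & !broken
  for (fam in unique(pf[is_unres])) {
    idx <- which(is_unres & pf == fam)
    pool <- descriptors[[fam]] %||% paste(fam, "product")
    out[idx] <- sample(pool, length(idx), replace = TRUE)
  }
  res <- which(!is_unres & !broken)
  if (length(res) > 0) {
    nm <- agent[res]
    syn <- !is.na(synonyms[nm]) & runif(length(res)) < 0.15
    nm[syn] <- synonyms[agent[res][syn]]
    out[res] <- paste0(nm, " ",
                       sample(strengths, length(res), replace = TRUE),
                       sample(forms, length(res), replace = TRUE),
                       sample(suffix, length(res), replace = TRUE))
  }
  brk <- which(broken)
  if (length(brk) > 0) {
    out[brk] <- sample(broken_pool, length(brk), replace = TRUE)
  }
  # practitioner noise: random casing and stray spacing, removed by
  # normalisation downstream
  u <- runif(n)
  out[u < 0.10] <- toupper(out[u < 0.10])
  dbl <- u > 0.95
  out[dbl] <- sub(" ", "  ", out[dbl])
  out
}

decoy_pool <- function() {
  c("consultation fee", "nail clip", "microchip implant", "bandage change",
    "cremation standard", "e-collar", "claw trim",
    "hills prescription diet 2kg",
    # excluded descriptions: diagnostic tests, consumables, refunds
    "phenobarbitone toxicity test", "insulin syringes x10",
    "refund - flea spot-on", "felv snap test")
}

#' Generate a synthetic consultation dataset with ground truth
#'
#' Draws a full synthetic EHR extract under a [synth_config()]: animals in
#' practices and sites, consultations with presenting complaints, planted
#' prescription events with free-text product descriptions (plus decoy and
#' excluded descriptions), and the ground truth needed to validate every
#' downstream stage: the expected Prescription Diversity of each practice's
#' generating class mix (`1 - sum(p^2)`, the large-sample value of the PD
#' estimator), the planted co-prescription blocks, and the planted event
#' count. Output is reproducible bit-for-bit under a fixed seed.
#'
#' @param config A `synth_config`.
#' @param seed Optional override of `config$seed`.
#' @return A list with `records` (tibble, one row per consultation x
#'   description) and `truth` (list: `true_pd`, `pc_probs`,
#'   `planted_groups`, `planted_event_count`, `n_broken`, `planted_events`,
#'   `practice_effects`, `config`).
#' @export
generate_dataset <- function(config = synth_config(), seed = NULL) {
  validate_synth_config(config)
  set.seed(seed %||% config$seed)
  tax <- config$taxonomy

  empty <- function() {
    records <- tibble::tibble(
      consultation_id = character(), animal_id = character(),
      species = character(), practice_id = character(),
      site_id = character(), date = as.Date(character()),
      mpc = character(), description = character()
    )
    truth <- list(
      true_pd = tibble::tibble(practice_id = character(), pf = character(),
                               true_pd = double()),
      pc_probs = tibble::tibble(practice_id = character(), pf = character(),
                                pc = character(), prob = double()),
      planted_groups = planted_groups_tbl(config),
      planted_event_count = 0L, n_broken = 0L,
      planted_events = tibble::tibble(),
      practice_effects = tibble::tibble(practice_id = character(),
                                        prescribe_prob = double()),
      config = config
    )
    list(records = records, truth = truth)
  }
  if (config$n_animals == 0) return(empty())

  ## practices and sites
  practice_id <- sprintf("P%03d", seq_len(config$n_practices))
  site_choices <- config$sites_per_practice
  if (length(site_choices) == 1) site_choices <- rep(site_choices, 2)
  n_sites <- sample(site_choices, config$n_practices, replace = TRUE)
  prescribe_p <- plogis(qlogis(config$prescribe_prob) +
                          rnorm(config$n_practices, 0, config$practice_sd))
  practice_effects <- tibble::tibble(practice_id = practice_id,
                                     prescribe_prob = prescribe_p)

  ## per-practice class mixes within each resolvable family
  resolvable <- tax[!is.na(tax$pc), c("pc", "pf")]
  resolvable <- unique(resolvable)
  profile_pfs <- unique(unlist(lapply(config$pf_profiles, names)))
  pc_probs_list <- list()
  for (fam in intersect(profile_pfs, unique(resolvable$pf))) {
    pcs <- resolvable$pc[resolvable$pf == fam]
    k <- length(pcs)
    alpha <- config$pc_concentration * (k:1) / sum(k:1)
    g <- matrix(stats::rgamma(config$n_practices * k,
                              shape = rep(alpha, each = config$n_practices)),
                nrow = config$n_practices)
    p <- g / rowSums(g)
    pc_probs_list[[fam]] <- tibble::tibble(
      practice_id = rep(practice_id, k),
      pf = fam,
      pc = rep(pcs, each = config$n_practices),
      prob = as.vector(p)
    )
  }
  pc_probs <- dplyr::bind_rows(pc_probs_list)
  true_pd <- dplyr::summarise(
    dplyr::group_by(pc_probs, .data$practice_id, .data$pf),
    true_pd = 1 - sum(.data$prob^2), .groups = "drop"
  )

  ## animals and consultations
  animal_practice <- sample(seq_len(config$n_practices), config$n_animals,
                            replace = TRUE)
  animal_site <- vapply(animal_practice, function(p) {
    sample.int(n_sites[p], 1)
  }, integer(1))
  animals <- tibble::tibble(
    animal_id = sprintf("A%06d", seq_len(config$n_animals)),
    species = sample(names(config$species_mix), config$n_animals,
                     replace = TRUE, prob = config$species_mix),
    practice_id = practice_id[animal_practice],
    site_id = sprintf("%s-S%d", practice_id[animal_practice], animal_site),
    n_consults = 1L + rpois(config$n_animals, config$consult_lambda)
  )
  consults <- animals[rep(seq_len(nrow(animals)), animals$n_consults),
                      c("animal_id", "species", "practice_id", "site_id")]
  n_con <- nrow(consults)
  consults$consultation_id <- sprintf("C%07d", seq_len(n_con))
  consults$date <- sample(seq(as.Date("2014-04-01"), as.Date("2016-03-31"),
                              by = "day"), n_con, replace = TRUE)
  consults$mpc <- sample(names(config$mpc_probs), n_con, replace = TRUE,
                         prob = config$mpc_probs)
  consults$prescribing <- runif(n_con) <
    prescribe_p[match(consults$practice_id, practice_id)]
  consults$block <- ifelse(consults$mpc %in% config$preventive_mpcs,
                           "preventive", "treatment")
  is_euth <- consults$prescribing & consults$block == "treatment" &
    runif(n_con) < config$euthanasia_rate
  consults$block[is_euth] <- "euthanasia"

  ## planted family sets per prescribing consultation
  set_rows <- list()
  for (blk in c("preventive", "treatment")) {
    idx <- which(consults$prescribing & consults$block == blk)
    if (length(idx) == 0) next
    profile <- config$pf_profiles[[blk]]
    m <- sample(seq_along(config$set_size_probs), length(idx),
                replace = TRUE, prob = config$set_size_probs)
    m <- pmin(m, length(profile))
    for (mm in sort(unique(m))) {
      sub <- idx[m == mm]
      picks <- sample_distinct_sets(names(profile), unname(profile), mm,
                                    length(sub))
      set_rows[[paste(blk, mm)]] <- tibble::tibble(
        consultation_id = rep(consults$consultation_id[sub], mm),
        pf = as.vector(picks)
      )
    }
    # rare between-block co-prescription
    other <- config$pf_profiles[[setdiff(c("preventive", "treatment"), blk)]]
    leak <- idx[runif(length(idx)) < config$leak_rate]
    if (length(leak) > 0) {
      set_rows[[paste(blk, "leak")]] <- tibble::tibble(
        consultation_id = consults$consultation_id[leak],
        pf = sample(names(other), length(leak), replace = TRUE, prob = other)
      )
    }
  }
  euth_idx <- which(consults$block == "euthanasia")
  if (length(euth_idx) > 0) {
    set_rows[["euthanasia"]] <- tibble::tibble(
      consultation_id = consults$consultation_id[euth_idx],
      pf = "euthanasia"
    )
  }
  planted <- dplyr::bind_rows(set_rows)
  if (nrow(planted) == 0) return(empty())
  planted <- dplyr::left_join(
    planted,
    consults[c("consultation_id", "practice_id")],
    by = "consultation_id"
  )

  ## resolve class, authorisation and agent for each planted event
  planted$pc <- NA_character_
  for (fam in unique(pc_probs$pf)) {
    idx <- which(planted$pf == fam)
    if (length(idx) == 0) next
    fam_probs <- pc_probs[pc_probs$pf == fam, , drop = FALSE]
    pcs <- unique(fam_probs$pc)
    # rows were built practice-fastest within class, so this reshapes to a
    # [practice, class] matrix with columns in `pcs` order
    pmat <- matrix(fam_probs$prob, nrow = config$n_practices)
    prn <- match(planted$practice_id[idx], practice_id)
    for (p in unique(prn)) {
      sub <- idx[prn == p]
      planted$pc[sub] <- sample(pcs, length(sub), replace = TRUE,
                                prob = pmat[p, ])
    }
  }
  unres_fams <- unique(tax$pf[tax$agent == "unresolved"])
  resolved_mask <- !is.na(planted$pc)
  planted$authorisation <- NA_character_
  planted$authorisation[resolved_mask] <- sample(
    names(config$authorisation_mix), sum(resolved_mask), replace = TRUE,
    prob = config$authorisation_mix
  )
  agent_key <- paste(tax$pc, tax$authorisation, sep = "|")
  planted$agent <- "unresolved"
  planted$agent[resolved_mask] <- tax$agent[match(
    paste(planted$pc[resolved_mask], planted$authorisation[resolved_mask],
          sep = "|"), agent_key)]
  if (anyNA(planted$agent)) {
    abort("taxonomy lacks an agent for a sampled (class, authorisation) pair",
          class = "pharmsurv_config_error")
  }
  bad_unres <- planted$agent == "unresolved" & !planted$pf %in% unres_fams
  if (any(bad_unres)) {
    abort("generator produced unresolved events outside the unresolved families",
          class = "pharmsurv_config_error")
  }
  planted$broken <- runif(nrow(planted)) < config$break_rate

  ## render text
  planted$description <- render_description(planted$agent, planted$pf,
                                            planted$broken)

  ## assemble records: prescriptions + decoys
  rx_rows <- dplyr::left_join(
    planted[c("consultation_id", "description")],
    consults[c("consultation_id", "animal_id", "species", "practice_id",
               "site_id", "date", "mpc")],
    by = "consultation_id"
  )
  decoy_for <- c(
    consults$consultation_id[!consults$prescribing],
    consults$consultation_id[consults$prescribing &
                               runif(n_con) < config$decoy_rate]
  )
  decoys <- dplyr::left_join(
    tibble::tibble(consultation_id = decoy_for,
                   description = sample(decoy_pool(), length(decoy_for),
                                        replace = TRUE)),
    consults[c("consultation_id", "animal_id", "species", "practice_id",
               "site_id", "date", "mpc")],
    by = "consultation_id"
  )
  records <- dplyr::bind_rows(rx_rows, decoys)
  records <- records[order(records$consultation_id), required_record_cols()]
  records <- tibble::as_tibble(records)

  truth <- list(
    true_pd = true_pd,
    pc_probs = pc_probs,
    planted_groups = planted_groups_tbl(config),
    planted_event_count = sum(!planted$broken),
    n_broken = sum(planted$broken),
    planted_events = tibble::as_tibble(planted),
    practice_effects = practice_effects,
    config = config
  )
  list(records = records, truth = truth)
}

planted_groups_tbl <- function(config) {
  blocks <- lapply(names(config$pf_profiles), function(b) {
    tibble::tibble(pf = names(config$pf_profiles[[b]]), block = b)
  })
  out <- dplyr::bind_rows(blocks)
  if (config$euthanasia_rate > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(pf = "euthanasia",
                                                block = "euthanasia"))
  }
  out
}
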