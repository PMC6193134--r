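#' Load a drug taxonomy from CSV
#'
#' Reads a taxonomy table mapping pharmaceutical agents to their
#' pharmaceutical class (PC), pharmaceutical family (PF) and authorisation
#' category, and validates the hierarchy. Each agent belongs to one PC and
#' each PC belongs to exactly one PF. Family-level descriptor entries (those
#' product descriptions that identify a family but not a specific agent, e.g.
#' generic vaccine booster wording) carry `agent = "unresolved"`, an empty
#' `pc` and an empty `authorisation`: their authorisation is reported
#' downstream as not estimable.
#'
#' @param source Path to a CSV file with header columns
#'   `agent,pc,pf,authorisation`, or a data frame with those columns.
#' @return A tibble with columns `agent`, `pc`, `pf`, `authorisation`
#'   (factor levels `veterinary`, `human`, `generic`; `NA` for unresolved
#'   entries). Empty `pc` strings become `NA`.
#' @export
#' @examples
#' tax <- load_taxonomy(data.frame(
#'   agent = "metronidazole", pc = "nitroimidazole",
#'   pf = "antibiotic", authorisation = "human"
#' ))
#' tax$pf
load_taxonomy <- function(source) {
  if (is.character(source)) {
    df <- read.csv(source, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    df <- as.data.frame(source, stringsAsFactors = FALSE)
  }
  required <- c("agent", "pc", "pf", "authorisation")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "taxonomy is missing column(s): ", paste(missing_cols, collapse = ", ")
    ), class = "pharmsurv_load_error")
  }
  df <- tibble::as_tibble(df[required])
  if (nrow(df) == 0) {
    warn("taxonomy file is empty; returning an empty taxonomy")
    df$authorisation <- factor(df$authorisation, levels = auth_levels())
    return(df)
  }
  for (col in required) df[[col]] <- trimws(as.character(df[[col]]))
  df$pc[df$pc == ""] <- NA_character_
  df$authorisation[df$authorisation == ""] <- NA_character_

  bad <- which(df$agent == "" | is.na(df$agent) | df$pf == "" | is.na(df$pf))
  if (length(bad) > 0) {
    abort(paste0("malformed taxonomy row(s): ", paste(bad, collapse = ", "),
                 " (agent and pf are required)"),
          class = "pharmsurv_load_error")
  }
  bad_auth <- which(!is.na(df$authorisation) &
                      !df$authorisation %in% auth_levels())
  if (length(bad_auth) > 0) {
    abort(paste0("unknown authorisation in taxonomy row(s): ",
                 paste(bad_auth, collapse = ", ")),
          class = "pharmsurv_load_error")
  }
  # resolvable agents must have a defined authorisation
  unres_auth <- which(df$agent != "unresolved" & is.na(df$authorisation))
  if (length(unres_auth) > 0) {
    abort(paste0("resolvable agent without authorisation in row(s): ",
                 paste(unres_auth, collapse = ", ")),
          class = "pharmsurv_load_error")
  }

  # family-level unresolved descriptors share agent/pc across families, so
  # uniqueness is checked on the full (agent, pc, pf) key
  dup <- duplicated(df[c("agent", "pc", "pf")])
  if (any(dup)) {
    abort(paste0("duplicate (agent, pc) pair(s) in taxonomy row(s): ",
                 paste(which(dup), collapse = ", ")),
          class = "pharmsurv_load_error")
  }
  # each PC maps to exactly one PF
  pc_pf <- unique(df[!is.na(df$pc), c("pc", "pf")])
  conflicted <- pc_pf$pc[duplicated(pc_pf$pc)]
  if (length(conflicted) > 0) {
    abort(paste0("pharmaceutical class(es) mapped to more than one family: ",
                 paste(unique(conflicted), collapse = ", ")),
          class = "pharmsurv_hierarchy_error")
  }
  df$authorisation <- factor(df$authorisation, levels = auth_levels())
  df
}

auth_levels <- function() c("veterinary", "human", "generic")

#' Load text-matching rules from CSV
#'
#' Rules come in two kinds. `exclusion_pattern` rules are regular expressions
#' that veto a product description before any identification is attempted
#' (diagnostic tests, consumables such as syringes, refunds).
#' `identification_string` rules are literal substrings, each pointing at one
#' taxonomy entry; they are matched case-insensitively against normalised
#' text.
#'
#' @param source Path to a CSV with header columns
#'   `kind,pattern,agent,priority` (an optional `pf` column disambiguates
#'   rules that target family-level `unresolved` entries), or a data frame
#'   with those columns.
#' @param taxonomy A taxonomy tibble from [load_taxonomy()]; every
#'   identification rule must reference one of its entries.
#' @return A tibble of validated rules with columns `kind`, `pattern`,
#'   `agent`, `pf`, `pc`, `authorisation`, `priority`. Exclusion regexes are
#'   compiled (test-matched) at load time so malformed patterns fail here,
#'   not at match time.
#' @export
load_rules <- function(source, taxonomy) {
  if (is.character(source)) {
    df <- read.csv(source, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    df <- as.data.frame(source, stringsAsFactors = FALSE)
  }
  required <- c("kind", "pattern", "agent", "priority")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("rules table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pharmsurv_load_error")
  }
  if (!"pf" %in% names(df)) df$pf <- NA_character_
  df <- tibble::as_tibble(df[c("kind", "pattern", "agent", "pf", "priority")])
  df$kind <- trimws(df$kind)
  df$agent <- trimws(as.character(df$agent))
  df$agent[df$agent == ""] <- NA_character_
  df$pf[!is.na(df$pf) & df$pf == ""] <- NA_character_
  df$priority <- as.integer(df$priority)

  bad_kind <- !df$kind %in% c("exclusion_pattern", "identification_string")
  if (any(bad_kind)) {
    abort(paste0("unknown rule kind in row(s): ",
                 paste(which(bad_kind), collapse = ", ")),
          class = "pharmsurv_load_error")
  }
  if (any(is.na(df$pattern) | df$pattern == "")) {
    abort("rules with empty patterns are not allowed",
          class = "pharmsurv_load_error")
  }
  for (k in unique(df$kind)) {
    pr <- df$priority[df$kind == k]
    if (anyNA(pr) || anyDuplicated(pr)) {
      abort(paste0("priorities must be unique integers within kind '", k, "'"),
            class = "pharmsurv_load_error")
    }
  }

  excl <- df$kind == "exclusion_pattern"
  if (any(!is.na(df$agent[excl]))) {
    abort("exclusion rules must not carry a target agent",
          class = "pharmsurv_load_error")
  }
  # compile exclusion regexes now; a bad pattern is a load error
  for (p in df$pattern[excl]) {
    ok <- tryCatch({ grepl(p, "probe", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) {
      abort(paste0("invalid exclusion regular expression: ", p),
            class = "pharmsurv_rule_compilation_error")
    }
  }

  ident <- which(!excl)
  if (any(is.na(df$agent[ident]))) {
    abort("identification rules must reference exactly one taxonomy agent",
          class = "pharmsurv_load_error")
  }
  # resolve identification targets against the taxonomy
  df$pc <- NA_character_
  df$authorisation <- factor(NA_character_, levels = auth_levels())
  for (i in ident) {
    hit <- taxonomy[taxonomy$agent == df$agent[i], , drop = FALSE]
    if (!is.na(df$pf[i])) hit <- hit[hit$pf == df$pf[i], , drop = FALSE]
    if (nrow(hit) == 0) {
      abort(paste0("identification rule '", df$pattern[i],
                   "' references unknown taxonomy entry: ", df$agent[i]),
            class = "pharmsurv_load_error")
    }
    if (nrow(hit) > 1) {
      abort(paste0("identification rule '", df$pattern[i],
                   "' matches several taxonomy entries for agent '",
                   df$agent[i], "'; add a pf column value to disambiguate"),
            class = "pharmsurv_load_error")
    }
    df$pf[i] <- hit$pf
    df$pc[i] <- hit$pc
    df$authorisation[i] <- hit$authorisation
  }
  df$pattern[!excl] <- normalise_text(df$pattern[!excl])
  df
}

#' Bundled example taxonomy
#'
#' A compact, synthetic drug taxonomy used by the synthetic-record generator
#' and the package examples: 13 pharmaceutical families, 25 pharmaceutical
#' classes and three agents per resolvable class, one for each authorisation
#' category (veterinary, human, generic). Agent names are plausible substance
#' names but the authorisation assignments are deliberately balanced rather
#' than faithful to any national formulary; the table is synthetic and should
#' not be used for real surveillance. The four families that real records
#' often describe only at family level (vaccine, euthanasia, neurological,
#' replacement agent) carry `unresolved` descriptor entries without a class
#' or authorisation.
#'
#' @return A taxonomy tibble as produced by [load_taxonomy()].
#' @export
#' @examples
#' tax <- example_taxonomy()
#' table(tax$pf)
example_taxonomy <- function() {
  pc_agents <- list(
    # pf, pc, veterinary, human, generic
    c("antibiotic", "aminopenicillin", "clavulanate-amoxicillin", "ampicillin", "amoxicillin"),
    c("antibiotic", "fluoroquinolone", "enrofloxacin", "ciprofloxacin", "ofloxacin"),
    c("antibiotic", "cephalosporin", "cefovecin", "ceftriaxone", "cephalexin"),
    c("antibiotic", "nitroimidazole", "carnidazole", "metronidazole", "tinidazole"),
    c("antibiotic", "tetracycline", "doxycycline", "minocycline", "oxytetracycline"),
    c("antibiotic", "trimethoprim sulfonamide", "trimethoprim-sulfadiazine", "co-trimoxazole", "sulfadiazine"),
    c("anti-inflammatory", "nsaid", "meloxicam", "ibuprofen", "carprofen"),
    c("anti-inflammatory", "corticosteroid", "prednisolone", "hydrocortisone", "dexamethasone"),
    c("antimycotic", "imidazole", "miconazole", "ketoconazole", "clotrimazole"),
    c("antimycotic", "polyene", "natamycin", "amphotericin", "nystatin"),
    c("antimycotic", "allylamine", "butenafine", "terbinafine", "naftifine"),
    c("gastrointestinal", "h2 antagonist", "cimetidine", "ranitidine", "famotidine"),
    c("gastrointestinal", "proton pump inhibitor", "pantoprazole", "esomeprazole", "omeprazole"),
    c("gastrointestinal", "prokinetic", "metoclopramide", "cisapride", "domperidone"),
    c("gastrointestinal", "antiemetic", "maropitant", "ondansetron", "prochlorperazine"),
    c("cardiovascular", "ace inhibitor", "benazepril", "enalapril", "ramipril"),
    c("cardiovascular", "inodilator", "pimobendan", "levosimendan", "digoxin"),
    c("cardiovascular", "diuretic", "torasemide", "spironolactone", "furosemide"),
    c("endocrine", "thyroid", "thiamazole", "carbimazole", "levothyroxine"),
    c("endocrine", "insulin", "insulin-lente", "insulin-glargine", "insulin-isophane"),
    c("ectoparasiticide", "neonicotinoid", "imidacloprid", "nitenpyram", "acetamiprid"),
    c("ectoparasiticide", "isoxazoline", "fluralaner", "afoxolaner", "sarolaner"),
    c("ectoparasiticide", "pyrethroid", "permethrin", "deltamethrin", "flumethrin"),
    c("ectoparasiticide", "insect growth regulator", "lufenuron", "methoprene", "pyriproxyfen"),
    c("endectocide", "milbemycin", "milbemycin-oxime", "moxidectin", "milbemycin"),
    c("endectocide", "avermectin", "selamectin", "doramectin", "ivermectin"),
    c("endoparasiticide", "quinoline", "praziquantel", "niclosamide", "epsiprantel"),
    c("endoparasiticide", "benzimidazole", "fenbendazole", "albendazole", "mebendazole"),
    c("endoparasiticide", "pyrimidine", "febantel", "oxantel", "pyrantel"),
    c("neurological", "opioid", "buprenorphine", "tramadol", "codeine"),
    c("neurological", "anticonvulsant", "phenobarbital", "levetiracetam", "gabapentin")
  )
  rows <- lapply(pc_agents, function(x) {
    tibble::tibble(
      agent = x[3:5], pc = x[2], pf = x[1],
      authorisation = c("veterinary", "human", "generic")
    )
  })
  resolved <- dplyr::bind_rows(rows)
  unresolved <- tibble::tibble(
    agent = "unresolved",
    pc = NA_character_,
    pf = c("vaccine", "euthanasia", "neurological", "replacement agent"),
    authorisation = NA_character_
  )
  load_taxonomy(dplyr::bind_rows(resolved, unresolved))
}

#' Bundled example matching rules
#'
#' The rule set paired with [example_taxonomy()]: one literal identification
#' string per agent (plus a handful of brand/descriptor synonyms such as
#' `metacam` and family-level vaccine or euthanasia wording), and exclusion
#' regexes for diagnostic tests, syringes and refunds.
#'
#' @return A rules tibble as produced by [load_rules()].
#' @export
example_rules <- function() {
  tax <- example_taxonomy()
  resolved <- tax[tax$agent != "unresolved", , drop = FALSE]
  ident <- tibble::tibble(
    kind = "identification_string",
    pattern = resolved$agent,
    agent = resolved$agent,
    pf = resolved$pf
  )
  extra <- tibble::tribble(
    ~pattern,            ~agent,          ~pf,
    "metacam",           "meloxicam",     "anti-inflammatory",
    "co-amox",           "amoxicillin",   "antibiotic",
    "vaccine",           "unresolved",    "vaccine",
    "vacc",              "unresolved",    "vaccine",
    "booster",           "unresolved",    "vaccine",
    "euthanasia",        "unresolved",    "euthanasia",
    "pentoject",         "unresolved",    "euthanasia",
    "pentobarbitone",    "unresolved",    "euthanasia",
    "sedative",          "unresolved",    "neurological",
    "hartmanns",         "unresolved",    "replacement agent",
    "vitamin b12",       "unresolved",    "replacement agent",
    "electrolyte",       "unresolved",    "replacement agent"
  )
  extra$kind <- "identification_string"
  ident <- dplyr::bind_rows(ident, extra[c("kind", "pattern", "agent", "pf")])
  ident$priority <- seq_len(nrow(ident))
  excl <- tibble::tibble(
    kind = "exclusion_pattern",
    pattern = c("\\btests?\\b", "syringe", "refund", "lab profile"),
    agent = NA_character_,
    pf = NA_character_,
    priority = 1:4
  )
  load_rules(dplyr::bind_rows(ident, excl), tax)
}
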