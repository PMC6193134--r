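#' Normalise a product description
#'
#' Canonical form used before any rule matching: lower case, all runs of
#' whitespace collapsed to a single space, leading/trailing space removed,
#' and typographic dash/quote variants standardised to their ASCII forms.
#' Idempotent.
#'
#' @param text Character vector of raw descriptions.
#' @return Character vector of canonical descriptions.
#' @export
#' @examples
#' normalise_text("  Metronidazole 400MG ")
normalise_text <- function(text) {
  out <- tolower(as.character(text))
  out <- gsub("[–—−]", "-", out)
  out <- gsub("[‘’]", "'", out)
  out <- gsub("\\s+", " ", out)
  trimws(out)
}

#' Test descriptions against exclusion rules
#'
#' Exclusion is evaluated before identification: a description that matches
#' any exclusion regex (diagnostic tests, consumables, refunds) yields no
#' prescriptions regardless of what else it contains.
#'
#' @param text Character vector of normalised descriptions.
#' @param rules Rules tibble from [load_rules()]; only its
#'   `exclusion_pattern` rows are used.
#' @return Logical vector: `TRUE` where the description is excluded.
#' @export
#' @examples
#' rules <- example_rules()
#' apply_exclusions(normalise_text("phenobarbitone toxicity test"), rules)
apply_exclusions <- function(text, rules) {
  patterns <- rules$pattern[rules$kind == "exclusion_pattern"]
  excluded <- rep(FALSE, length(text))
  for (p in patterns) {
    excluded <- excluded | grepl(p, text, perl = TRUE)
  }
  excluded
}

# Match identification strings against a vector of unique normalised texts.
# Returns a tibble (text = index into `texts`, rule = row index into `rules`)
# after the nested-pattern rule: if two patterns match and one is a substring
# of the other with an occurrence lying inside an occurrence of the longer,
# only the longer is kept (e.g. "co-amoxiclav" beats "amox").
match_identification <- function(texts, rules) {
  ident_idx <- which(rules$kind == "identification_string")
  if (length(ident_idx) == 0 || length(texts) == 0) {
    return(tibble::tibble(text = integer(), rule = integer()))
  }
  pats <- rules$pattern[ident_idx]
  hit_list <- lapply(pats, function(p) {
    which(stringr::str_detect(texts, stringr::fixed(p)))
  })
  hits <- tibble::tibble(
    text = unlist(hit_list),
    rule = rep(ident_idx, lengths(hit_list))
  )
  if (nrow(hits) == 0) return(hits)

  multi <- unique(hits$text[duplicated(hits$text)])
  drop <- logical(nrow(hits))
  for (tx in multi) {
    rows <- which(hits$text == tx)
    rls <- hits$rule[rows]
    pat <- rules$pattern[rls]
    occ <- gregexpr2(texts[tx], pat)
    for (a in seq_along(rows)) {
      for (b in seq_along(rows)) {
        if (a == b || drop[rows[a]]) next
        # drop a if pattern a is a strict substring of pattern b and one of
        # its occurrences is nested inside an occurrence of b
        if (nchar(pat[a]) < nchar(pat[b]) &&
            grepl(pat[a], pat[b], fixed = TRUE) &&
            any(outer(occ[[a]], occ[[b]],
                      function(sa, sb) sa >= sb &
                        sa + nchar(pat[a]) <= sb + nchar(pat[b])))) {
          drop[rows[a]] <- TRUE
        }
      }
    }
  }
  hits[!drop, , drop = FALSE]
}

# all fixed-match start positions of each pattern in a single text
gregexpr2 <- function(text, patterns) {
  lapply(patterns, function(p) {
    m <- gregexpr(p, text, fixed = TRUE)[[1]]
    as.integer(m[m > 0])
  })
}

#' Identify prescriptions in product descriptions
#'
#' Applies the two-stage procedure to one or more descriptions: exclusion
#' regexes first, then literal identification strings, with nested matches
#' resolved in favour of the longer pattern and results de-duplicated at
#' taxonomy-entry level. A description may legitimately yield several
#' matches (combination/multivalent products).
#'
#' @param text Character vector of descriptions (normalised internally).
#' @param rules Rules tibble from [load_rules()].
#' @param taxonomy Taxonomy tibble (used only for validation of rule
#'   targets; targets are already resolved at rule load).
#' @return A tibble with one row per (description, matched taxonomy entry):
#'   columns `description_text`, `pattern`, `agent`, `pc`, `pf`,
#'   `authorisation`. Excluded or unmatched descriptions contribute no rows.
#' @export
#' @examples
#' identify_prescriptions("1x dog annual booster", example_rules())
identify_prescriptions <- function(text, rules, taxonomy = NULL) {
  txt <- normalise_text(text)
  keep <- !apply_exclusions(txt, rules) & txt != ""
  hits <- match_identification(ifelse(keep, txt, NA_character_), rules)
  out <- tibble::tibble(
    description_text = txt[hits$text],
    pattern = rules$pattern[hits$rule],
    agent = rules$agent[hits$rule],
    pc = rules$pc[hits$rule],
    pf = rules$pf[hits$rule],
    authorisation = rules$authorisation[hits$rule]
  )
  dplyr::distinct(out, .data$description_text, .data$agent, .data$pc,
                  .data$pf, .keep_all = TRUE)
}

required_record_cols <- function() {
  c("consultation_id", "animal_id", "species", "practice_id", "site_id",
    "date", "mpc", "description")
}

#' Map consultation records to prescription events
#'
#' Runs the full text-mining pass over a consultation table: normalise each
#' free-text product description, drop excluded descriptions, match
#' identification strings, and emit one prescription event per
#' (consultation, distinct taxonomy entry) pair. Raw multiplicity (the same
#' entry matched by several description lines of one consultation) is kept
#' in `n_descriptions`.
#'
#' @param records Tibble with one row per (consultation, description):
#'   columns `consultation_id`, `animal_id`, `species`, `practice_id`,
#'   `site_id`, `date`, `mpc`, `description`. Consultation-level metadata
#'   must be internally consistent per consultation id.
#' @param rules Rules tibble from [load_rules()].
#' @param taxonomy Taxonomy tibble from [load_taxonomy()].
#' @return A tibble of prescription events with the consultation metadata
#'   plus `agent`, `pc`, `pf`, `authorisation`, `n_descriptions`. The
#'   attribute `"mapping_summary"` (see [mapping_summary()]) counts unique
#'   descriptions that were excluded, matched and unmatched.
#' @export
map_consultations <- function(records, rules, taxonomy) {
  missing_cols <- setdiff(required_record_cols(), names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records are missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pharmsurv_validation_error")
  }
  meta_cols <- setdiff(required_record_cols(), "description")
  meta <- dplyr::distinct(records[meta_cols])
  if (anyDuplicated(meta$consultation_id)) {
    abort("consultation ids with conflicting metadata in records",
          class = "pharmsurv_validation_error")
  }

  txt <- normalise_text(records$description)
  utext <- unique(txt)
  excluded <- apply_exclusions(utext, rules)
  hits <- match_identification(ifelse(excluded, NA_character_, utext), rules)

  matched_text <- unique(hits$text)
  summary <- tibble::tibble(
    n_unique_descriptions = length(utext),
    n_excluded = sum(excluded),
    n_matched = length(matched_text),
    n_unmatched = length(utext) - sum(excluded) - length(matched_text)
  )

  lookup <- tibble::tibble(
    text_id = hits$text,
    agent = rules$agent[hits$rule],
    pc = rules$pc[hits$rule],
    pf = rules$pf[hits$rule],
    authorisation = rules$authorisation[hits$rule]
  )
  per_row <- tibble::tibble(
    consultation_id = records$consultation_id,
    text_id = match(txt, utext)
  )
  events <- dplyr::inner_join(per_row, lookup, by = "text_id",
                              relationship = "many-to-many")
  events <- dplyr::count(events, .data$consultation_id, .data$agent,
                         .data$pc, .data$pf, .data$authorisation,
                         name = "n_descriptions")
  events <- dplyr::inner_join(meta, events, by = "consultation_id")
  events <- dplyr::arrange(events, .data$consultation_id, .data$pf,
                           .data$agent)
  attr(events, "mapping_summary") <- summary
  events
}

#' Retrieve the mapping coverage summary
#'
#' @param events Event tibble returned by [map_consultations()].
#' @return A one-row tibble with counts of unique descriptions seen,
#'   excluded, matched and unmatched.
#' @export
mapping_summary <- function(events) {
  s <- attr(events, "mapping_summary")
  if (is.null(s)) {
    abort("no mapping summary attached; was this produced by map_consultations()?",
          class = "pharmsurv_validation_error")
  }
  s
}
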