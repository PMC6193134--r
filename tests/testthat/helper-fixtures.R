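# small hand-built fixtures shared across tests

tiny_taxonomy <- function() {
  load_taxonomy(data.frame(
    agent = c("metronidazole", "enrofloxacin", "amoxicillin",
              "clavulanate-amoxicillin", "meloxicam", "milbemycin-oxime",
              "praziquantel", "unresolved"),
    pc = c("nitroimidazole", "fluoroquinolone", "aminopenicillin",
           "aminopenicillin", "nsaid", "milbemycin", "quinoline", ""),
    pf = c("antibiotic", "antibiotic", "antibiotic", "antibiotic",
           "anti-inflammatory", "endectocide", "endoparasiticide",
           "vaccine"),
    authorisation = c("human", "veterinary", "generic", "veterinary",
                      "veterinary", "veterinary", "veterinary", "")
  ))
}

tiny_rules <- function(taxonomy = tiny_taxonomy()) {
  load_rules(data.frame(
    kind = c(rep("identification_string", 8), rep("exclusion_pattern", 3)),
    pattern = c("metronidazole", "enrofloxacin", "amox",
                "clavulanate-amoxicillin", "meloxicam", "milbemycin-oxime",
                "praziquantel", "booster",
                "toxicity test", "syringe", "refund"),
    agent = c("metronidazole", "enrofloxacin", "amoxicillin",
              "clavulanate-amoxicillin", "meloxicam", "milbemycin-oxime",
              "praziquantel", "unresolved", NA, NA, NA),
    pf = c(rep(NA, 7), "vaccine", NA, NA, NA),
    priority = c(1:8, 1:3)
  ), taxonomy)
}

# a minimal consultation-records tibble; descriptions is a list, one
# character vector per consultation
make_records <- function(descriptions, species = "dog",
                         practice_id = "P001", site_id = NULL,
                         animal_id = NULL) {
  n <- length(descriptions)
  species <- rep_len(species, n)
  practice_id <- rep_len(practice_id, n)
  site_id <- rep_len(site_id %||% paste0(practice_id, "-S1"), n)
  animal_id <- rep_len(animal_id %||% sprintf("A%03d", seq_len(n)), n)
  rows <- lapply(seq_len(n), function(i) {
    tibble::tibble(
      consultation_id = sprintf("C%03d", i),
      animal_id = animal_id[i],
      species = species[i],
      practice_id = practice_id[i],
      site_id = site_id[i],
      date = as.Date("2015-01-01") + i,
      mpc = "other unwell",
      description = descriptions[[i]]
    )
  })
  dplyr::bind_rows(rows)
}
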