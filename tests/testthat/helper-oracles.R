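# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# probability that two prescriptions drawn without replacement belong to
# different classes, by exhaustive enumeration of ordered pairs
oracle_pd <- function(counts) {
  labels <- rep(seq_along(counts), counts)
  n <- length(labels)
  if (n < 2) return(NA_real_)
  diff_pairs <- 0L
  total <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      total <- total + 1L
      if (labels[i] != labels[j]) diff_pairs <- diff_pairs + 1L
    }
  }
  diff_pairs / total
}

# exact two-sided Wilcoxon rank-sum p-value by enumerating every assignment
# of the pooled ranks to group A (tie-free samples only)
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n_a <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(length(pooled), n_a)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# tie-corrected Kendall tau by O(n^2) pair counting
oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  concordant <- discordant <- tie_x <- tie_y <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tie_x <- tie_x + 1L; tie_y <- tie_y + 1L }
      else if (dx == 0) tie_x <- tie_x + 1L
      else if (dy == 0) tie_y <- tie_y + 1L
      else if (dx == dy) concordant <- concordant + 1L
      else discordant <- discordant + 1L
    }
  }
  n0 <- n * (n - 1) / 2
  (concordant - discordant) /
    sqrt((n0 - tie_x) * (n0 - tie_y))
}

# edge weights by a double loop over consultations and family pairs
oracle_edge_weights <- function(sets) {
  weights <- list()
  for (cid in unique(sets$consultation_id)) {
    fams <- sort(unique(sets$pf[sets$consultation_id == cid]))
    if (length(fams) < 2) next
    for (i in seq_len(length(fams) - 1)) {
      for (j in (i + 1):length(fams)) {
        key <- paste(fams[i], fams[j], sep = "|")
        weights[[key]] <- (weights[[key]] %||% 0L) + 1L
      }
    }
  }
  weights
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all start positions of fixed pattern `p` in text `t` by sliding comparison
oracle_occurrences <- function(t, p) {
  np <- nchar(p); nt <- nchar(t)
  if (np > nt) return(integer(0))
  which(vapply(seq_len(nt - np + 1),
               function(i) substr(t, i, i + np - 1) == p, logical(1)))
}

# identification by scanning every rule against the text, then the stated
# nested-pattern and entry-level dedup rules
oracle_identify <- function(text, rules) {
  txt <- tolower(trimws(gsub("\\s+", " ", text)))
  excl <- rules[rules$kind == "exclusion_pattern", , drop = FALSE]
  for (p in excl$pattern) if (grepl(p, txt, perl = TRUE)) {
    return(rules[0, c("agent", "pc", "pf")])
  }
  ident <- rules[rules$kind == "identification_string", , drop = FALSE]
  occ <- lapply(ident$pattern, function(p) oracle_occurrences(txt, p))
  matched <- which(lengths(occ) > 0)
  keep <- matched
  for (a in matched) {
    for (b in matched) {
      if (a == b) next
      pa <- ident$pattern[a]; pb <- ident$pattern[b]
      if (nchar(pa) < nchar(pb) && length(oracle_occurrences(pb, pa)) > 0) {
        nested <- any(vapply(occ[[a]], function(sa) {
          any(sa >= occ[[b]] & sa + nchar(pa) <= occ[[b]] + nchar(pb))
        }, logical(1)))
        if (nested) keep <- setdiff(keep, a)
      }
    }
  }
  unique(ident[keep, c("agent", "pc", "pf")])
}
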