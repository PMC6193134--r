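#' Per-consultation sets of distinct pharmaceutical families
#'
#' Collapses prescription events to one row per (consultation, family),
#' keeping the number of underlying events: a family prescribed twice in a
#' consultation contributes once to co-prescription but both events to node
#' size.
#'
#' @param events Prescription events from [map_consultations()].
#' @param level `"pf"` (default) or `"pc"` for a class-level network
#'   (class-unresolved events are dropped at class level).
#' @return Tibble (`consultation_id`, `pf`, `n_events`).
#' @export
consult_pf_sets <- function(events, level = c("pf", "pc")) {
  level <- match.arg(level)
  if (level == "pc") {
    events <- events[!is.na(events$pc), , drop = FALSE]
    events$pf <- events$pc
  }
  if (!"n_descriptions" %in% names(events)) events$n_descriptions <- 1L
  dplyr::summarise(
    dplyr::group_by(events, .data$consultation_id, .data$pf),
    n_events = sum(.data$n_descriptions),
    .groups = "drop"
  )
}

#' Co-prescription rate
#'
#' Fraction of prescribing consultations in which two or more distinct
#' pharmaceutical families were prescribed.
#'
#' @param sets Tibble from [consult_pf_sets()].
#' @return A proportion in \[0, 1\].
#' @export
coprescription_rate <- function(sets) {
  if (nrow(sets) == 0) {
    abort("no prescribing consultations; co-prescription rate undefined",
          class = "pharmsurv_undefined_result")
  }
  sizes <- table(sets$consultation_id)
  mean(sizes >= 2)
}

#' Build the co-prescription network
#'
#' Nodes are pharmaceutical families sized by their total prescription
#' events; an edge between two families gains one unit of weight for every
#' consultation in which both were prescribed (so a consultation carrying
#' `m` families contributes all `choose(m, 2)` pairs).
#'
#' @param sets Tibble from [consult_pf_sets()]; an `n_events` column is
#'   optional (defaults to one event per row).
#' @return A list of class `corx_network`: `nodes` (tibble `pf`, `n`),
#'   `edges` (tibble `from`, `to`, `weight` with `from < to`), `groups`
#'   (`NULL` until [detect_groups()]).
#' @export
build_network <- function(sets) {
  if (nrow(sets) == 0) {
    abort("cannot build a network from zero consultations",
          class = "pharmsurv_validation_error")
  }
  if (!"n_events" %in% names(sets)) sets$n_events <- 1L
  sets <- dplyr::distinct(sets, .data$consultation_id, .data$pf,
                          .keep_all = TRUE)
  nodes <- dplyr::summarise(dplyr::group_by(sets, .data$pf),
                            n = sum(.data$n_events), .groups = "drop")
  pairs <- dplyr::inner_join(
    sets[c("consultation_id", "pf")], sets[c("consultation_id", "pf")],
    by = "consultation_id", suffix = c("_a", "_b"),
    relationship = "many-to-many"
  )
  pairs <- pairs[pairs$pf_a < pairs$pf_b, , drop = FALSE]
  edges <- dplyr::count(pairs, from = .data$pf_a, to = .data$pf_b,
                        name = "weight")
  structure(list(nodes = nodes, edges = tibble::as_tibble(edges),
                 groups = NULL),
            class = "corx_network")
}

#' @export
print.corx_network <- function(x, ...) {
  cat(sprintf("co-prescription network: %d nodes, %d edges, total weight %d\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  if (!is.null(x$groups)) {
    cat(sprintf("groups: %d\n", length(unique(x$groups$group))))
  }
  invisible(x)
}

#' Sparsify a co-prescription network
#'
#' Applies the two reference pruning rules in order: first drop families
#' contributing less than `node_frac` (default 0.5%) of total prescriptions;
#' then, over the edges between surviving nodes, drop edges whose weight
#' does not exceed the mean surviving edge weight (strict inequality).
#' Nodes left without edges are retained as isolates — a family prescribed
#' alone (euthanasia, typically) is a finding, not noise.
#'
#' @param network A `corx_network`.
#' @param node_frac Minimum node share of total prescriptions.
#' @return The sparsified `corx_network`.
#' @export
sparsify <- function(network, node_frac = 0.005) {
  total <- sum(network$nodes$n)
  keep <- network$nodes$n >= node_frac * total
  if (!any(keep)) {
    warn("all nodes fall below the prescription-share threshold")
  }
  nodes <- network$nodes[keep, , drop = FALSE]
  edges <- network$edges[network$edges$from %in% nodes$pf &
                           network$edges$to %in% nodes$pf, , drop = FALSE]
  if (nrow(edges) > 0) {
    edges <- edges[edges$weight > mean(edges$weight), , drop = FALSE]
  }
  structure(list(nodes = nodes, edges = edges, groups = NULL),
            class = "corx_network")
}

# one asynchronous label-propagation sweep sequence; labels flow along
# weighted edges until every node's label has (weak) majority support
label_propagation_run <- function(pfs, edge_idx, max_iter = 100) {
  n <- length(pfs)
  labels <- seq_len(n)
  if (nrow(edge_idx) == 0 || n == 0) return(labels)
  nbrs <- vector("list", n)
  wts <- vector("list", n)
  for (i in seq_len(nrow(edge_idx))) {
    a <- edge_idx$from[i]; b <- edge_idx$to[i]; w <- edge_idx$weight[i]
    nbrs[[a]] <- c(nbrs[[a]], b); wts[[a]] <- c(wts[[a]], w)
    nbrs[[b]] <- c(nbrs[[b]], a); wts[[b]] <- c(wts[[b]], w)
  }
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (v in sample.int(n)) {
      if (is.null(nbrs[[v]])) next
      support <- tapply(wts[[v]], labels[nbrs[[v]]], sum)
      best <- as.integer(names(support)[support == max(support)])
      if (!labels[v] %in% best) {
        labels[v] <- if (length(best) == 1) best else sample(best, 1)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels
}

#' Detect co-prescription groups by label propagation
#'
#' Runs asynchronous label propagation — every node starts with a unique
#' label and repeatedly adopts the label carrying the greatest total edge
#' weight among its neighbours, in random order, until consensus — and
#' repeats it `n_runs` times under a fixed seed. The modal partition across
#' runs is returned (ties resolved in favour of the earliest run), which
#' pins down the algorithm's inherent update-order randomness. Isolated
#' nodes always form singleton groups, and disconnected components are never
#' merged (labels can only travel along edges).
#'
#' @param network A sparsified `corx_network`.
#' @param seed Integer seed driving the update orders.
#' @param n_runs Number of independent runs entering the consensus.
#' @return The network with `groups` set: a tibble (`pf`, `group`) where
#'   group ids are integers numbered by first appearance over
#'   alphabetically sorted families.
#' @export
detect_groups <- function(network, seed = 1L, n_runs = 20L) {
  pfs <- sort(network$nodes$pf)
  edge_idx <- tibble::tibble(
    from = match(network$edges$from, pfs),
    to = match(network$edges$to, pfs),
    weight = network$edges$weight
  )
  set.seed(seed)
  partitions <- vapply(seq_len(n_runs), function(run) {
    canonical_partition(label_propagation_run(pfs, edge_idx))
  }, character(1))
  tab <- table(partitions)
  modal <- names(tab)[tab == max(tab)]
  winner <- if (length(modal) == 1) modal else
    partitions[min(which(partitions %in% modal))]
  group <- as.integer(strsplit(winner, ",", fixed = TRUE)[[1]])
  network$groups <- tibble::tibble(pf = pfs, group = group)
  network
}

# canonical signature of a labelling: groups renumbered by first appearance
canonical_partition <- function(labels) {
  ids <- match(labels, unique(labels))
  paste(ids, collapse = ",")
}

#' Convert a co-prescription network to an igraph object
#'
#' @param network A `corx_network`.
#' @return An undirected weighted `igraph` graph with vertex attribute `n`
#'   (prescription count) and, when groups have been detected, `group`.
#' @export
as_igraph <- function(network) {
  vertices <- network$nodes
  if (!is.null(network$groups)) {
    vertices <- dplyr::left_join(vertices, network$groups, by = "pf")
  }
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = vertices)
}

#' Export a co-prescription network to disk
#'
#' Writes a GraphML file, a weighted edge-list CSV (`source,target,weight`)
#' and, when groups are present, a groups CSV (`pf,group`).
#'
#' @param network A `corx_network`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, dir, prefix = "coprescription") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  gml <- file.path(dir, paste0(prefix, ".graphml"))
  igraph::write_graph(as_igraph(network), gml, format = "graphml")
  paths <- c(paths, gml)
  edges_csv <- file.path(dir, paste0(prefix, "_edges.csv"))
  edges <- network$edges
  names(edges) <- c("source", "target", "weight")
  write.csv(edges, edges_csv, row.names = FALSE)
  paths <- c(paths, edges_csv)
  if (!is.null(network$groups)) {
    groups_csv <- file.path(dir, paste0(prefix, "_groups.csv"))
    write.csv(network$groups, groups_csv, row.names = FALSE)
    paths <- c(paths, groups_csv)
  }
  invisible(paths)
}
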