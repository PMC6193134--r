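sets_from <- function(...) {
  fams <- list(...)
  dplyr::bind_rows(lapply(seq_along(fams), function(i) {
    tibble::tibble(consultation_id = sprintf("C%03d", i), pf = fams[[i]])
  }))
}

test_that("per-consultation family sets de-duplicate within consultation", {
  ev <- tibble::tibble(
    consultation_id = c("C1", "C1", "C1", "C2"),
    pf = c("antibiotic", "antibiotic", "anti-inflammatory", "vaccine"),
    pc = NA_character_,
    n_descriptions = 1L
  )
  sets <- consult_pf_sets(ev)
  expect_equal(nrow(sets), 3)
  c1 <- sets[sets$consultation_id == "C1", ]
  expect_setequal(c1$pf, c("antibiotic", "anti-inflammatory"))
  # both antibiotic events count toward node size
  expect_equal(c1$n_events[c1$pf == "antibiotic"], 2L)
})

test_that("co-prescription rate is the share of multi-family consultations", {
  expect_equal(coprescription_rate(sets_from("A", "B", "C")), 0)
  expect_equal(coprescription_rate(
    sets_from(c("A", "B"), "A", c("A", "B", "C"))), 2 / 3)
  expect_error(coprescription_rate(sets_from()[0, ]),
               class = "pharmsurv_undefined_result")
})

test_that("network construction counts nodes by events and edges by pairs", {
  net1 <- build_network(sets_from(c("AB", "AF")))
  expect_equal(nrow(net1$edges), 1)
  expect_equal(net1$edges$weight, 1L)
  net3 <- build_network(sets_from(c("AB", "AF", "V")))
  expect_equal(nrow(net3$edges), choose(3, 2))
  expect_equal(net3$edges$weight, rep(1L, 3))
})

test_that("edge weights equal the brute-force pair count on random sets", {
  set.seed(101)
  fams <- LETTERS[1:8]
  sets <- dplyr::bind_rows(lapply(1:100, function(i) {
    tibble::tibble(consultation_id = sprintf("C%03d", i),
                   pf = sample(fams, sample(1:4, 1)))
  }))
  net <- build_network(sets)
  want <- oracle_edge_weights(sets)
  got <- setNames(net$edges$weight, paste(net$edges$from, net$edges$to,
                                          sep = "|"))
  expect_equal(sort(names(got)), sort(names(want)))
  for (k in names(want)) expect_equal(unname(got[k]), want[[k]])
  # conservation: total edge weight = sum over sets of choose(m, 2)
  m <- table(sets$consultation_id)
  expect_equal(sum(net$edges$weight), sum(choose(m, 2)))
})

test_that("sparsification applies the node share and strict edge-mean rules", {
  net <- build_network(sets_from(c("A", "B"), c("A", "B"), c("A", "B"),
                                 c("A", "B"), c("A", "C"), c("B", "C")))
  # push node C below 0.5% by inflating A and B counts
  net$nodes$n[net$nodes$pf %in% c("A", "B")] <- 1000L
  sp <- sparsify(net)
  expect_false("C" %in% sp$nodes$pf)
  # edges touching removed nodes are gone before the mean rule applies
  expect_true(all(sp$edges$from != "C" & sp$edges$to != "C"))

  # arithmetic oracle for the edge rule: weights (1, 1, 4), mean 2 -> only 4
  net2 <- build_network(sets_from(c("A", "B"), c("A", "C"), c("B", "C"),
                                  c("A", "B"), c("A", "B"), c("A", "B")))
  sp2 <- sparsify(net2, node_frac = 0)
  expect_equal(nrow(sp2$edges), 1)
  expect_equal(sp2$edges$weight, 4L)
  # nodes left edgeless are retained as isolates
  expect_setequal(sp2$nodes$pf, c("A", "B", "C"))

  # second application removes no nodes (shares only grow)
  sp3 <- sparsify(sp2)
  expect_setequal(sp3$nodes$pf, sp2$nodes$pf)
})

test_that("label propagation recovers cliques, isolates and components", {
  clique <- function(members, id0) {
    dplyr::bind_rows(lapply(1:6, function(i) {
      tibble::tibble(consultation_id = sprintf("Q%s%02d", id0, i),
                     pf = members)
    }))
  }
  sets <- dplyr::bind_rows(clique(c("A", "B", "C"), "x"),
                           clique(c("D", "E", "F"), "y"))
  net <- build_network(sets)
  out <- detect_groups(net, seed = 3)
  g <- setNames(out$groups$group, out$groups$pf)
  expect_equal(length(unique(g)), 2)
  expect_equal(length(unique(g[c("A", "B", "C")])), 1)
  expect_equal(length(unique(g[c("D", "E", "F")])), 1)
  # disconnected components are never merged
  expect_false(g[["A"]] == g[["D"]])
  # a lone isolate is its own group
  iso <- build_network(sets_from("Z"))
  expect_equal(detect_groups(iso, seed = 1)$groups$group, 1L)
})

test_that("group detection is invariant to renaming the families", {
  set.seed(11)
  cfg <- synth_config(n_practices = 6, n_animals = 800, seed = 23)
  sim <- generate_dataset(cfg)
  ev <- map_consultations(sim$records, cfg$rules, cfg$taxonomy)
  sp <- sparsify(build_network(consult_pf_sets(ev)))
  out1 <- detect_groups(sp, seed = 5)$groups
  perm <- setNames(paste0("zz_", rev(sort(sp$nodes$pf))), sort(sp$nodes$pf))
  sp2 <- sp
  sp2$nodes$pf <- unname(perm[sp2$nodes$pf])
  sp2$edges$from2 <- unname(perm[sp2$edges$from])
  sp2$edges$to2 <- unname(perm[sp2$edges$to])
  sp2$edges$from <- pmin(sp2$edges$from2, sp2$edges$to2)
  sp2$edges$to <- pmax(sp2$edges$from2, sp2$edges$to2)
  out2 <- detect_groups(sp2, seed = 5)$groups
  # same partition as sets of families, modulo the renaming
  part <- function(tb) unname(lapply(split(tb$pf, tb$group), sort))
  mapped <- lapply(part(out2), function(grp) {
    sort(names(perm)[match(grp, perm)])
  })
  expect_setequal(lapply(part(out1), paste, collapse = ","),
                  lapply(mapped, paste, collapse = ","))
})

test_that("our label propagation agrees with igraph on a clear topology", {
  # independent cross-check against the reference implementation
  sets <- dplyr::bind_rows(lapply(1:20, function(i) {
    tibble::tibble(consultation_id = sprintf("B%02d", i),
                   pf = if (i <= 10) c("A", "B", "C") else c("D", "E"))
  }))
  net <- detect_groups(build_network(sets), seed = 2)
  ig <- as_igraph(net)
  set.seed(2)
  comm <- igraph::cluster_label_prop(ig, weights = igraph::E(ig)$weight)
  ours <- setNames(net$groups$group, net$groups$pf)
  theirs <- setNames(igraph::membership(comm),
                     igraph::V(ig)$name)[names(ours)]
  # identical partitions up to label names
  expect_equal(length(unique(ours)), length(unique(theirs)))
  for (grp in unique(ours)) {
    members <- names(ours)[ours == grp]
    expect_equal(length(unique(theirs[members])), 1)
  }
})

test_that("network export writes GraphML, edge list and groups", {
  dir <- withr::local_tempdir()
  sets <- sets_from(c("A", "B"), c("A", "B"), c("B", "C"))
  net <- detect_groups(build_network(sets), seed = 1)
  paths <- write_network(net, dir)
  expect_true(all(file.exists(file.path(
    dir, c("coprescription.graphml", "coprescription_edges.csv",
           "coprescription_groups.csv")))))
  edges <- read.csv(file.path(dir, "coprescription_edges.csv"))
  expect_equal(names(edges), c("source", "target", "weight"))
  g <- igraph::read_graph(file.path(dir, "coprescription.graphml"),
                          format = "graphml")
  expect_equal(igraph::gorder(g), 3)
})
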