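test_that("co-occurrence links require a shared collection point", {
  df <- occ_df(c("A", "B", "B", "C"), c("p1", "p1", "p2", "p2"))
  net <- cooccurrence_network(read_occurrences(df))
  expect_setequal(apply(as_edgelist(net), 1, paste, collapse = "-"),
                  c("A-B", "B-C"))

  tri <- cooccurrence_network(read_occurrences(
    occ_df(c("A", "B", "C"), rep("p1", 3))))
  expect_equal(ecount(tri), 3L)

  expect_error(cooccurrence_network(read_occurrences(occ_df("A", "p1"))),
               "fewer than 2")
})

test_that("bipartite networks link taxa to environments and formations", {
  df <- occ_df(c("A", "B"), c("p1", "p2"), formation = c("F1", "F2"),
               environments = c("lagoon;offshore_shelf", "lagoon"))
  tab <- read_occurrences(df)
  env_net <- bipartite_network(tab, "environments")
  expect_equal(unname(degree(env_net)["A"]), 2)
  expect_false(are_adjacent(env_net, "B", "offshore_shelf"))

  form_net <- bipartite_network(tab, "formations")
  expect_true(are_adjacent(form_net, "A", "F1"))
  expect_false(are_adjacent(form_net, "A", "F2"))
  expect_error(bipartite_network(tab, "environments",
                                 taxa_subset = character(0)),
               "input error")
})

test_that("one-mode projection links nodes sharing a neighbor", {
  df <- occ_df(c("A", "B", "C"), c("p1", "p2", "p3"),
               formation = c("F1", "F1", "F2"))
  net <- bipartite_network(read_occurrences(df), "formations")
  proj <- one_mode_projection(net, "taxon")
  expect_true(are_adjacent(proj, "A", "B"))
  expect_equal(unname(degree(proj)["C"]), 0)
  expect_error(one_mode_projection(net, "environment"), "parameter error")

  # star bipartite: one formation, k taxa -> k-clique
  k <- 5
  star <- bipartite_network(read_occurrences(
    occ_df(paste0("t", 1:k), paste0("p", 1:k), formation = "F1")),
    "formations")
  clique <- one_mode_projection(star, "taxon")
  expect_equal(ecount(clique), k * (k - 1) / 2)
})

test_that("projection agrees with a brute-force shared-neighbor scan", {
  for (s in 1:5) {
    g <- withr::with_seed(s, sample_bipartite(6, 8, p = 0.3))
    V(g)$name <- paste0(ifelse(V(g)$type, "b", "a"), seq_len(vcount(g)))
    V(g)$node_class <- ifelse(V(g)$type, "taxon", "formation")
    net <- netbiostrat:::as_fossil_network(g, bipartite = TRUE,
                                           classes = c("formation", "taxon"))
    proj <- one_mode_projection(net, "taxon")
    taxa <- V(g)$name[V(g)$type]
    for (i in seq_along(taxa)) {
      for (j in seq_len(i - 1L)) {
        shared <- length(intersect(
          names(neighbors(g, taxa[i])), names(neighbors(g, taxa[j])))) > 0
        expect_equal(are_adjacent(proj, taxa[i], taxa[j]), shared)
      }
    }
  }
})

test_that("degree centrality ignores self-loops", {
  g <- graph_from_literal(a - b, a - c, simplify = FALSE)
  g <- add_edges(g, c("a", "a"))
  expect_equal(unname(degree_centrality(g)["a"]), 2)
  g2 <- make_star(6, mode = "undirected")
  V(g2)$name <- paste0("v", 1:6)
  expect_equal(unname(degree_centrality(g2)["v1"]), 5)
  iso <- make_empty_graph(1, directed = FALSE)
  V(iso)$name <- "x"
  expect_equal(unname(degree_centrality(iso)["x"]), 0)
})

test_that("betweenness matches exhaustive shortest-path enumeration", {
  path3 <- graph_from_literal(a - b, b - c)
  bc <- betweenness_centrality(path3)
  expect_equal(unname(bc["b"]), 1)
  expect_equal(unname(bc["a"]), 0)

  ring <- make_ring(4)
  V(ring)$name <- paste0("v", 1:4)
  expect_true(all(abs(betweenness_centrality(ring) -
                        betweenness_centrality(ring)[1]) < 1e-12))

  for (s in 1:4) {
    g <- random_graph(10, 0.3, seed = s)
    expect_equal(betweenness_centrality(g), bruteforce_betweenness(g),
                 tolerance = 1e-10)
  }
})

test_that("assortativity behaves on assortative, disassortative and degenerate cases", {
  # two disjoint cliques, attribute = clique id -> perfectly assortative
  g <- disjoint_union(make_full_graph(4), make_full_graph(4))
  V(g)$name <- paste0("v", 1:8)
  V(g)$clique <- rep(c("one", "two"), each = 4)
  expect_equal(assortativity_coefficient(g, "clique"), 1)

  # complete bipartite between two categories: direct formula evaluation
  kb <- make_full_bipartite_graph(3, 3)
  V(kb)$name <- paste0("v", 1:6)
  V(kb)$cat <- rep(c("x", "y"), each = 3)
  r <- assortativity_coefficient(kb, "cat")
  # mixing matrix e = [[0, .5], [.5, 0]]; r = (tr(e) - sum(e^2)) / (1 - sum(e^2))
  expect_equal(r, (0 - 0.5) / (1 - 0.5))

  V(kb)$cat2 <- "same"
  expect_warning(r2 <- assortativity_coefficient(kb, "cat2"), "undefined")
  expect_true(is.na(r2))
  # regular graph: degree assortativity undefined, signalled
  expect_warning(r3 <- assortativity_coefficient(make_ring(6), "degree"),
                 "undefined")
  expect_true(is.na(r3))
})

test_that("network export and import round-trips structure and attributes", {
  df <- occ_df(c("A", "B", "B", "C"), c("p1", "p1", "p2", "p2"))
  net <- cooccurrence_network(read_occurrences(df))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path)
  back <- read_network(path)
  expect_setequal(V(back)$name, V(net)$name)
  expect_equal(ecount(back), ecount(net))
  expect_equal(sort(V(back)$node_class), sort(V(net)$node_class))
})
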