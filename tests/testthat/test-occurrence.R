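test_that("reading collapses duplicate occurrences and validates structure", {
  df <- occ_df(c("taxA", "taxA", "taxB"), c("pt1", "pt1", "pt1"))
  tab <- read_occurrences(df)
  expect_s3_class(tab, "occurrence_table")
  expect_equal(nrow(tab$occurrences), 2L)
  expect_setequal(tab$taxa$name, c("taxA", "taxB"))

  expect_error(read_occurrences(df[, c("taxon", "collection_id")]),
               "schema error")
  expect_error(read_occurrences(df[0, ]), "empty")
  df_bad <- occ_df("taxA", "pt1", formation = "")
  expect_error(read_occurrences(df_bad), "formation")
})

test_that("per-occurrence environments are unioned into per-taxon sets", {
  df <- occ_df(c("taxA", "taxA", "taxB"), c("pt1", "pt2", "pt1"),
               environments = c("offshore_shelf", "lower_shoreface;lagoon",
                                ""))
  tab <- read_occurrences(df)
  expect_setequal(tab$taxon_environments$taxA,
                  c("offshore_shelf", "lower_shoreface", "lagoon"))
  expect_length(tab$taxon_environments$taxB, 0L)
})

test_that("unknown categorical codes are reported, not rejected", {
  vocab <- load_vocabularies()
  df <- occ_df(c("taxA", "taxB"), c("pt1", "pt1"),
               environments = c("atlantis_shelf", "lagoon"))
  tab <- read_occurrences(df, vocab = vocab)
  expect_equal(attr(tab, "unknown_codes")$environments, "atlantis_shelf")
})

test_that("index-taxa filter removes flagged and companionless taxa", {
  df <- occ_df(c("disc1", "taxA", "taxB", "loner"),
               c("pt1", "pt1", "pt1", "pt2"),
               formation = c("F1", "F1", "F1", "F2"))
  df$flags <- c("disc_shaped", "", "", "")
  tab <- read_occurrences(df)
  filt <- filter_index_taxa(tab)
  expect_setequal(filt$taxa$name, c("taxA", "taxB"))
  rep <- attr(filt, "removal_report")
  expect_equal(rep$flagged, "disc1")
  expect_equal(rep$no_cooccurrence, "loner")
})

test_that("a taxon alone at its point but sharing a formation is retained", {
  df <- occ_df(c("taxA", "taxB"), c("pt1", "pt2"),
               formation = c("F1", "F1"))
  filt <- filter_index_taxa(read_occurrences(df))
  expect_setequal(filt$taxa$name, c("taxA", "taxB"))
})

test_that("filter cascades when a removal strands its only companion", {
  # taxB co-occurs only with flagged disc1; removing disc1 leaves taxB alone
  df <- occ_df(c("disc1", "taxB", "taxC", "taxD"),
               c("pt1", "pt1", "pt2", "pt2"),
               formation = c("F1", "F1", "F2", "F2"))
  df$flags <- c("disc_shaped", "", "", "")
  filt <- filter_index_taxa(read_occurrences(df))
  expect_setequal(filt$taxa$name, c("taxC", "taxD"))
})

test_that("index-taxa filter is idempotent on generated tables", {
  for (s in c(2, 9)) {
    tab <- generate_occurrences(synthetic_config(
      n_biozones = 2L, formations_per_biozone = 4L, taxon_pool_size = 15L,
      collections_per_formation = c(3L, 6L), seed = s))$table
    once <- filter_index_taxa(tab)
    twice <- filter_index_taxa(once)
    expect_identical(once$occurrences, twice$occurrences)
    expect_identical(once$taxa$name, twice$taxa$name)
  }
})

test_that("incidence bookkeeping identities hold", {
  df <- occ_df(c("t1", "t2", "t1", "t2"), c("p1", "p1", "p2", "p2"))
  inc <- build_incidence(read_occurrences(df), "collection_point")
  expect_equal(dim(unclass(inc)), c(2L, 2L))
  st <- incidence_stats(inc)
  expect_equal(st$Q[2], 2L)

  for (s in 1:3) {
    tab <- generate_occurrences(synthetic_config(
      n_biozones = 2L, formations_per_biozone = 4L, taxon_pool_size = 20L,
      collections_per_formation = c(3L, 6L), seed = s))$table
    for (unit in c("collection_point", "formation")) {
      inc <- build_incidence(tab, unit)
      st <- incidence_stats(inc)
      # direct recount from the raw matrix
      m <- unclass(inc)
      expect_equal(sum(seq_along(st$Q) * st$Q), sum(rowSums(m > 0)))
      expect_equal(st$S_obs, sum(st$Q))
      expect_true(all(st$Y >= 1 & st$Y <= st$N))
    }
  }
})

test_that("formation selection keeps rich formations and drops orphans", {
  df <- occ_df(paste0("t", c(1:5, 1, 6)),
               c(rep("p1", 5), "p2", "p2"),
               formation = c(rep("F1", 5), "F2", "F2"))
  inc <- build_incidence(read_occurrences(df), "formation")
  sel <- select_formations(inc, 5L)
  expect_equal(colnames(unclass(sel)), "F1")
  expect_false("t6" %in% rownames(unclass(sel)))

  expect_identical(unclass(select_formations(inc, 1L)), unclass(inc))
  expect_error(select_formations(inc, 10L), "input error")
  expect_error(select_formations(inc, 0L), "parameter error")
})

test_that("written tables round-trip exactly", {
  gen <- generate_occurrences(synthetic_config(
    n_biozones = 2L, formations_per_biozone = 3L, taxon_pool_size = 12L,
    collections_per_formation = c(3L, 5L), seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(gen$table, path)
  back <- read_occurrences(path)
  ord <- function(df) df[order(df$taxon, df$collection_id), ]
  expect_equal(ord(back$occurrences), ord(gen$table$occurrences),
               ignore_attr = TRUE)
  expect_equal(back$taxa[order(back$taxa$name), ],
               gen$table$taxa[order(gen$table$taxa$name), ],
               ignore_attr = TRUE)
  expect_equal(back$taxon_environments[sort(names(back$taxon_environments))],
               gen$table$taxon_environments[
                 sort(names(gen$table$taxon_environments))])
})
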