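make_edges <- function() {
  tibble::tibble(molecule_id = c("m1", "m1", "m2"),
                 microbe_id = c("o1", "o2", "o2"),
                 mz = c(100.5, 100.5, 250.1),
                 test = "fisher",
                 statistic = c(12, 8, 5),
                 p_value = c(1e-12, 1e-8, 1e-6),
                 sign = c("positive", "negative", "positive"))
}

test_that("the network has exactly the incident nodes and is bipartite", {
  net <- build_network(make_edges())
  expect_equal(igraph::vcount(net), 4L)
  expect_equal(igraph::ecount(net), 3L)
  expect_setequal(igraph::V(net)$name, c("m1", "m2", "o1", "o2"))
  expect_true(igraph::is_bipartite(net))
  kinds <- setNames(igraph::V(net)$kind, igraph::V(net)$name)
  ends <- igraph::ends(net, igraph::E(net))
  expect_true(all(kinds[ends[, 1]] != kinds[ends[, 2]]))
  # molecule nodes carry m/z
  expect_equal(igraph::V(net)$mz[igraph::V(net)$name == "m1"], 100.5)
  # an id on both sides is rejected
  bad <- make_edges()
  bad$microbe_id[1] <- "m2"
  expect_error(build_network(bad), "bipartite")
  # empty edge list -> empty network
  empty <- build_network(make_edges()[0, ])
  expect_equal(igraph::vcount(empty), 0L)
})

test_that("connected modules are size-filtered components, largest first", {
  e <- tibble::tibble(molecule_id = c("m1", "m2", "m2", "m3"),
                      microbe_id = c("o1", "o2", "o3", "o4"),
                      mz = NA_real_, test = "fisher", statistic = 1,
                      p_value = 1e-12, sign = "positive")
  net <- build_network(e)
  mods <- connected_modules(net, min_size = 2L)
  expect_length(mods, 3L)
  expect_equal(lengths(mods), c(3L, 2L, 2L))
  expect_setequal(mods[[1]], c("m2", "o2", "o3"))
  expect_length(connected_modules(net, min_size = 4L), 0L)
  # a star is one module
  star <- tibble::tibble(molecule_id = paste0("m", 1:5), microbe_id = "o1",
                         mz = NA_real_, test = "fisher", statistic = 1,
                         p_value = 1e-12, sign = "positive")
  smod <- connected_modules(build_network(star), 2L)
  expect_length(smod, 1L)
  expect_length(smod[[1]], 6L)
  # components partition the node set
  expect_setequal(unlist(connected_modules(net, 1L)), igraph::V(net)$name)
})

test_that("GraphML and edge-TSV exports round-trip the network", {
  net <- build_network(make_edges(),
                       taxonomy = c(o1 = "k__B;p__F", o2 = "k__B;p__P"))
  for (fmt in c("graphml", "edge_tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(net, path, fmt)
    back <- import_network(path, fmt)
    expect_equal(igraph::vcount(back), igraph::vcount(net))
    expect_equal(igraph::ecount(back), igraph::ecount(net))
    ord <- match(igraph::V(net)$name, igraph::V(back)$name)
    expect_false(anyNA(ord))
    expect_equal(igraph::V(back)$mz[ord], igraph::V(net)$mz)
    eo <- order(igraph::E(back)$p_value)
    en <- order(igraph::E(net)$p_value)
    expect_equal(igraph::E(back)$p_value[eo], igraph::E(net)$p_value[en])
    # sign survives as "positive"/"negative" strings
    expect_setequal(unique(igraph::E(back)$sign), c("positive", "negative"))
  }
  expect_error(export_network(net, tempfile(), "dot"), "unknown")
})

test_that("an empty network still exports valid GraphML", {
  net <- build_network(make_edges()[0, ])
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, path, "graphml")
  back <- import_network(path, "graphml")
  expect_equal(igraph::vcount(back), 0L)
  expect_equal(igraph::ecount(back), 0L)
})

test_that("planted components pair one molecule with one microbe", {
  inp <- planted_scan_inputs(seed = 41, n_planted = 15L)
  edges <- association_scan(inp$mol, inp$mic, "fisher", 1e-10)
  net <- build_network(edges)
  mods <- connected_modules(net, 2L)
  kinds <- setNames(igraph::V(net)$kind, igraph::V(net)$name)
  planted_key <- paste(inp$truth$planted$molecule_id,
                       inp$truth$planted$microbe_id)
  for (m in mods) {
    mols <- m[kinds[m] == "molecule"]
    mics <- m[kinds[m] == "microbe"]
    expect_equal(length(mols), 1L)
    expect_equal(length(mics), 1L)
    expect_true(paste(mols, mics) %in% planted_key)
  }
})

test_that("collapsing by taxonomy prefix merges family-level nodes", {
  e <- make_edges()
  net <- build_network(e)
  key <- c(o1 = "family_X", o2 = "family_X")
  cg <- collapse_nodes(net, key)
  expect_equal(igraph::vcount(cg), 3L)
  expect_true("family_X" %in% igraph::V(cg)$name)
  # parallel edges keep the smallest P value
  pmin_edge <- igraph::E(cg)$p_value[
    igraph::get_edge_ids(cg, c("m1", "family_X"))]
  expect_equal(pmin_edge, 1e-12)
})
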