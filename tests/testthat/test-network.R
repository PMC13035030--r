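test_that("build_network applies thresholds and keeps seed nodes", {
  sets <- list(
    c("fehlinformation", "a", "b"),
    c("fehlinformation", "a", "b"),
    c("desinformation", "b", "c")
  )
  tab <- compute_frequencies(make_sentences(sets))
  net <- build_network(tab, config = run_config(min_edge_count = 1))
  expect_true(all(c("fehlinformation", "desinformation") %in%
                    net$nodes$lemma))
  # a-b co-occur twice, b-c once
  expect_equal(net$edges$weight[net$edges$from == "a" & net$edges$to == "b"],
               2)
  expect_equal(net$edges$weight[net$edges$from == "b" & net$edges$to == "c"],
               1)
  # seed sizes are 1; non-seed sizes are their frequencies
  expect_equal(net$nodes$size[net$nodes$lemma == "fehlinformation"], 1)
  expect_equal(net$nodes$size[net$nodes$lemma == "a"], 2 / 3)

  # raising the threshold only removes edges (monotonicity)
  net2 <- build_network(tab, config = run_config(min_edge_count = 2))
  key <- function(n) paste(n$edges$from, n$edges$to)
  expect_true(all(key(net2) %in% key(net)))
  expect_lt(nrow(net2$edges), nrow(net$edges))

  # no pair and no seed link meets the threshold: empty network error
  expect_error(build_network(tab, config = run_config(min_edge_count = 10)),
               "empty network")
})

test_that("modularity closed forms hold at gamma 1 and 0.5", {
  tri2 <- two_triangles()
  one <- stats::setNames(rep(1L, 6), tri2$nodes$lemma)
  expect_equal(modularity_score(tri2, one, resolution = 1), 0)
  expect_equal(modularity_score(tri2, one, resolution = 0.5), 0.5)
  natural <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                             c("a", "b", "c", "d", "e", "f"))
  expect_equal(modularity_score(tri2, natural, resolution = 1), 0.5)
  # invariance to community relabeling
  relabeled <- stats::setNames(c(7L, 7L, 7L, 3L, 3L, 3L),
                               c("a", "b", "c", "d", "e", "f"))
  expect_equal(modularity_score(tri2, relabeled, resolution = 1), 0.5)
  # missing node is named in the error
  expect_error(modularity_score(tri2, natural[-2], resolution = 1), "b")
})

test_that("modularity agrees with igraph's resolution-scaled implementation", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    edges <- withr::with_seed(300 + s, {
      n <- 8
      pairs <- t(utils::combn(letters[1:n], 2))
      keep <- stats::runif(nrow(pairs)) < 0.4
      data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                 weight = sample(1:5, sum(keep), replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    if (nrow(edges) < 3) next
    net <- semnet(sort(unique(c(edges$from, edges$to))), edges)
    m <- withr::with_seed(s, stats::setNames(
      sample(1:3, nrow(net$nodes), replace = TRUE), net$nodes$lemma))
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes$lemma)
    for (gamma in c(0.5, 1, 1.5)) {
      expect_equal(
        modularity_score(net, m, resolution = gamma),
        igraph::modularity(g, m[igraph::V(g)$name],
                           weights = igraph::E(g)$weight,
                           resolution = gamma),
        tolerance = 1e-12)
    }
  }
})

test_that("louvain recovers planted structure on canonical small graphs", {
  tri2 <- two_triangles()
  p <- louvain(tri2, run_config(resolution = 1, rng_seed = 4))
  m <- p$membership
  expect_equal(length(unique(m)), 2L)
  expect_equal(length(unique(m[c("a", "b", "c")])), 1L)
  expect_equal(length(unique(m[c("d", "e", "f")])), 1L)
  expect_equal(p$modularity, 0.5)

  # complete graph: a single community at gamma 1
  k5 <- graph_fixture(t(utils::combn(letters[1:5], 2)))
  pk <- louvain(k5, run_config(resolution = 1, rng_seed = 4))
  expect_equal(length(unique(pk$membership)), 1L)

  # reported Q equals recomputed Q (self-consistency)
  expect_equal(pk$modularity, modularity_score(k5, pk))
})

test_that("gamma near zero yields one community on any connected graph", {
  path6 <- graph_fixture(cbind(letters[1:5], letters[2:6]))
  p <- louvain(path6, run_config(resolution = 1e-9, rng_seed = 1))
  expect_equal(length(unique(p$membership)), 1L)
})

test_that("louvain attains the exhaustive-enumeration optimum on small graphs", {
  battery <- list(
    two_triangles = list(net = two_triangles(), gamma = 1),
    two_triangles_lowres = list(net = two_triangles(), gamma = 0.5),
    k5 = list(net = graph_fixture(t(utils::combn(letters[1:5], 2))),
              gamma = 1),
    path5 = list(net = graph_fixture(cbind(letters[1:4], letters[2:5])),
                 gamma = 1),
    star6 = list(net = graph_fixture(cbind("a", letters[2:6])), gamma = 1),
    barbell = list(net = graph_fixture(rbind(
      c("a", "b"), c("a", "c"), c("b", "c"),
      c("c", "d"),
      c("d", "e"), c("d", "f"), c("e", "f"))), gamma = 1),
    weighted_pair = list(net = semnet(letters[1:4], data.frame(
      from = c("a", "b", "c", "a"), to = c("b", "c", "d", "d"),
      weight = c(5, 1, 5, 1))), gamma = 1)
  )
  for (nm in names(battery)) {
    case <- battery[[nm]]
    p <- louvain(case$net, run_config(resolution = case$gamma, rng_seed = 2))
    best <- oracle_best_modularity(case$net, case$gamma)
    expect_equal(p$modularity, best, tolerance = 1e-12,
                 label = sprintf("louvain Q on '%s'", nm),
                 expected.label = "exhaustive optimum")
  }
})

test_that("louvain never scores below the all-singletons partition", {
  for (s in 1:5) {
    edges <- withr::with_seed(500 + s, {
      pairs <- t(utils::combn(letters[1:7], 2))
      keep <- stats::runif(nrow(pairs)) < 0.45
      data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                 weight = sample(1:4, sum(keep), replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    if (nrow(edges) < 2) next
    net <- semnet(sort(unique(c(edges$from, edges$to))), edges)
    p <- louvain(net, run_config(resolution = 0.7, rng_seed = s))
    singletons <- stats::setNames(seq_len(nrow(net$nodes)), net$nodes$lemma)
    expect_gte(p$modularity,
               modularity_score(net, singletons, resolution = 0.7))
    # community ids are dense integers starting at 0
    expect_equal(sort(unique(unname(p$membership))),
                 seq_len(length(unique(p$membership))) - 1L)
  }
})

test_that("identical seeds give identical partitions", {
  net <- two_triangles()
  p1 <- louvain(net, run_config(rng_seed = 99))
  p2 <- louvain(net, run_config(rng_seed = 99))
  expect_identical(p1, p2)
})

test_that("rank_clusters orders by size with documented tie-breaks", {
  nodes <- data.frame(
    lemma = c(letters[1:5], letters[6:8], letters[9:11]),
    size = c(rep(0.2, 5), c(0.9, 0.8, 0.7), c(0.1, 0.1, 0.1)),
    is_seed = FALSE, stringsAsFactors = FALSE)
  edges <- data.frame(from = c("a", "f", "i"), to = c("b", "g", "j"),
                      weight = 1)
  net <- semnet(nodes, edges)
  m <- stats::setNames(c(rep(0L, 5), rep(1L, 3), rep(2L, 3)), nodes$lemma)
  part <- structure(list(membership = m, resolution = 1,
                         modularity = 0, rng_seed = 1),
                    class = "semnet_partition")
  rep_ <- rank_clusters(part, net)
  expect_equal(rep_$n_nodes, c(5, 3, 3))
  expect_equal(rep_$cluster_id, c(0L, 1L, 2L))  # 2.4 > 0.3 breaks the 3-3 tie
  expect_equal(rep_$rank, 1:3)
  # members sorted by node size descending
  expect_equal(rep_$members[2], "f; g; h")

  # singleton-only partition: lexicographic order via first-lemma tie-break
  m2 <- stats::setNames(0:10, nodes$lemma)
  part2 <- structure(list(membership = m2, resolution = 1,
                          modularity = 0, rng_seed = 1),
                     class = "semnet_partition")
  rep2 <- rank_clusters(part2, net)
  same_size <- rep2[rep2$total_size == 0.1, ]
  expect_equal(same_size$members, sort(same_size$members))
})

test_that("GEXF export round-trips nodes, edges, weights and attributes", {
  sets <- list(c("fehlinformation", "a", "b"),
               c("desinformation", "a", "b"),
               c("fehlinformation", "b", "c"))
  tab <- compute_frequencies(make_sentences(sets))
  net <- build_network(tab)
  part <- louvain(net, run_config(rng_seed = 5))
  f <- tempfile(fileext = ".gexf")
  write_gexf(net, part, f)
  back <- read_gexf(f)
  expect_equal(back$nodes$lemma, net$nodes$lemma)
  expect_identical(back$nodes$size, net$nodes$size)  # full precision
  expect_equal(stats::setNames(back$nodes$modularity_class,
                               back$nodes$lemma),
               part$membership)
  expect_equal(back$edges[c("from", "to")], net$edges[c("from", "to")])
  expect_identical(back$edges$weight, net$edges$weight)

  # byte-identical across reruns
  f2 <- tempfile(fileext = ".gexf")
  write_gexf(net, louvain(net, run_config(rng_seed = 5)), f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))

  # empty partition on a non-empty network violates the precondition
  empty <- structure(list(membership = stats::setNames(integer(0),
                                                       character(0)),
                          resolution = 0.5, modularity = NA, rng_seed = 1),
                     class = "semnet_partition")
  expect_error(write_gexf(net, empty, tempfile()), "empty")
})
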