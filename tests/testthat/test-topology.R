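test_that("top-k selection ranks by absolute strength with stable ties", {
  e <- data.frame(source = c("a", "b", "c", "a"),
                  target = c("b", "c", "d", "c"),
                  strength = c(3, -5, 2, -2))
  net <- mock_network(e)
  expect_identical(top_k_edges(net, 1)$edges$strength, -5)
  # |2| ties broken lexicographically by (source, target): a->c before c->d
  two <- top_k_edges(net, 3)$edges
  expect_identical(two$source, c("b", "a", "a"))
  expect_identical(top_k_edges(net, 100)$edges, net$edges[
    order(-abs(net$edges$strength), net$edges$source, net$edges$target), ,
    drop = FALSE] |> (\(d) { rownames(d) <- NULL; d })())
  expect_identical(top_k_edges(top_k_edges(net, 2), 2)$edges,
                   top_k_edges(net, 2)$edges)
  expect_error(top_k_edges(net, 0), ">= 1")
})

test_that("in-degree counts incoming edges, including isolated nodes", {
  star <- mock_network(data.frame(source = letters[1:5], target = "hub",
                                  strength = 1), taxa = c(letters[1:5], "hub", "iso"))
  d <- in_degree(star)
  expect_equal(unname(d["hub"]), 5)
  expect_equal(unname(d["iso"]), 0)

  empty <- mock_network(data.frame(source = character(), target = character(),
                                   strength = numeric()), taxa = letters[1:4])
  expect_true(all(in_degree(empty) == 0))

  set.seed(14)
  n <- 10
  adj <- matrix(runif(n * n) < 0.3 & !diag(n), n,
                dimnames = list(letters[1:n], letters[1:n]))
  idx <- which(adj, arr.ind = TRUE)
  net <- mock_network(data.frame(source = rownames(adj)[idx[, 1]],
                                 target = colnames(adj)[idx[, 2]],
                                 strength = 1), taxa = letters[1:n])
  expect_equal(unname(in_degree(net)[letters[1:n]]), unname(colSums(adj)))
  expect_equal(unname(out_degree(net)[letters[1:n]]), unname(rowSums(adj)))
  expect_equal(sum(in_degree(net)), nrow(net$edges))
})

test_that("betweenness matches exhaustive path enumeration", {
  path <- mock_network(data.frame(source = c("a", "b"), target = c("b", "c"),
                                  strength = 1))
  b <- betweenness_centrality(path)
  expect_equal(unname(b[c("a", "b", "c")]), c(0, 1, 0))

  nodes <- letters[1:4]
  cmpl <- expand.grid(source = nodes, target = nodes,
                      stringsAsFactors = FALSE)
  cmpl <- cmpl[cmpl$source != cmpl$target, ]
  cmpl$strength <- 1
  expect_true(all(betweenness_centrality(mock_network(cmpl)) == 0))

  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:6, 1)
    adj <- matrix(runif(n * n) < 0.4 & !diag(n), n,
                  dimnames = list(letters[1:n], letters[1:n]))
    idx <- which(adj, arr.ind = TRUE)
    if (!nrow(idx)) next
    net <- mock_network(data.frame(source = rownames(adj)[idx[, 1]],
                                   target = colnames(adj)[idx[, 2]],
                                   strength = 1), taxa = letters[1:n])
    got <- betweenness_centrality(net)
    want <- brute_betweenness(adj * 1)
    expect_equal(got[names(want)], want, tolerance = 1e-9,
                 info = paste("seed", seed))
  }
})

test_that("eigenvector centrality matches a dense eigen-solver", {
  nodes <- letters[1:5]
  cmpl <- expand.grid(source = nodes, target = nodes,
                      stringsAsFactors = FALSE)
  cmpl <- cmpl[cmpl$source != cmpl$target, ]
  cmpl$strength <- 1
  expect_equal(unname(eigenvector_centrality(mock_network(cmpl))),
               rep(1, 5))

  star <- mock_network(data.frame(source = "hub", target = letters[1:6],
                                  strength = 1))
  ec <- eigenvector_centrality(star)
  expect_equal(unname(ec["hub"]), 1)
  leaves <- ec[letters[1:6]]
  expect_true(all(abs(leaves - leaves[1]) < 1e-8) && all(leaves < 1))

  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:12, 1)
    # ring plus random chords keeps the symmetrized graph connected
    ring <- data.frame(source = letters[1:n],
                       target = letters[c(2:n, 1)], strength = 1)
    extra <- data.frame(source = sample(letters[1:n], n, TRUE),
                        target = sample(letters[1:n], n, TRUE), strength = 1)
    e <- rbind(ring, extra)
    e <- e[e$source != e$target, ]
    e <- e[!duplicated(paste(e$source, e$target)), ]
    net <- mock_network(e, taxa = letters[1:n])
    adj <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    adj[cbind(match(e$source, letters[1:n]), match(e$target, letters[1:n]))] <- 1
    got <- eigenvector_centrality(net)
    want <- eigen_oracle(adj)
    expect_equal(unname(got), unname(want), tolerance = 1e-6,
                 info = paste("seed", seed))
  }

  edgeless <- mock_network(data.frame(source = character(),
                                      target = character(),
                                      strength = numeric()),
                           taxa = letters[1:3])
  expect_true(all(eigenvector_centrality(edgeless) == 0))

  expect_error(eigenvector_centrality(star, max_iter = 1),
               "did not converge within 1")
})

test_that("influential report ranks by eigenvector and flags sinks", {
  e <- data.frame(source = c("a", "b", "c", "d"),
                  target = c("hub", "hub", "hub", "a"),
                  strength = c(2, 1, 1, 1))
  net <- mock_network(e)
  rep <- influential_report(net)
  expect_identical(rep$taxon[1], "hub")
  expect_true(rep$low_out_degree[rep$taxon == "hub"])  # hub never acts
  expect_identical(colnames(rep),
                   c("taxon", "in_degree", "out_degree", "betweenness",
                     "eigenvector", "low_out_degree"))
  expect_identical(nrow(influential_report(net, top_n = 3)), 3L)

  single <- mock_network(data.frame(source = "a", target = "b",
                                    strength = 1), taxa = c("a", "b"))
  expect_identical(influential_report(single)$taxon[1], "a")

  # permuting node and edge order does not change the ranking
  perm <- net
  perm$taxa <- rev(perm$taxa)
  perm$edges <- perm$edges[c(3, 1, 4, 2), ]
  expect_equal(influential_report(perm), rep)
})

test_that("GraphML and GEXF exports carry the network", {
  e <- data.frame(source = c("a", "b"), target = c("b", "c"),
                  strength = c(1.5, -2))
  net <- mock_network(e)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(back), 3)
  expect_equal(igraph::gsize(back), 2)
  expect_equal(sort(igraph::E(back)$strength), c(-2, 1.5))

  gexf <- withr::local_tempfile(fileext = ".gexf")
  export_gexf(net, gexf)
  txt <- readLines(gexf)
  expect_identical(sum(grepl("<node id=", txt)), 3L)
  expect_identical(sum(grepl("<edge id=", txt)), 2L)
})
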