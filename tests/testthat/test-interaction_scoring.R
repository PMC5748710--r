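test_that("MIS is the maximum edge score into the target set", {
  net <- toy_network()
  expect_equal(max_interaction_score("g", c("a", "b"), net), 700L)
  expect_equal(max_interaction_score("g", c("a", "b", "c"), net), 999L)
  expect_equal(max_interaction_score("b", "c", net), 0L)     # no edge: sentinel
  expect_equal(max_interaction_score("g", gene_set(c("a", "b"), "t"), net),
               700L)
  expect_error(max_interaction_score("zz", c("a"), net), "not a network node")
})

test_that("a gene never matches itself when it belongs to the target set", {
  net <- toy_network()
  # g is in the set; only the g-a edge may count
  expect_equal(max_interaction_score("g", c("g", "a"), net), 400L)
  expect_equal(max_interaction_score("g", "g", net), 0L)
})

test_that("random-set sampling is reproducible, seed-sensitive, and uniform in
           shape", {
  net <- ppi_network(random_edge_table(30L, 80L, 1L))
  rs1 <- sample_random_sets(net, set_size = 5L, n_sets = 20L, seed = 42L)
  rs2 <- sample_random_sets(net, set_size = 5L, n_sets = 20L, seed = 42L)
  rs3 <- sample_random_sets(net, set_size = 5L, n_sets = 20L, seed = 43L)
  expect_identical(rs1$sets, rs2$sets)
  expect_false(identical(rs1$sets, rs3$sets))
  expect_true(all(vapply(rs1$sets, function(s)
    length(unique(s)) == 5L, logical(1L))))
  expect_true(all(unlist(rs1$sets) %in% net$nodes))

  # set size equal to the universe forces every set to be the whole universe
  full <- sample_random_sets(net, set_size = n_nodes(net), n_sets = 3L,
                             seed = 1L)
  for (s in full$sets) expect_setequal(s, net$nodes)
  expect_error(sample_random_sets(net, set_size = n_nodes(net) + 1L,
                                  n_sets = 3L, seed = 1L), "exceeds")
})

test_that("exceedance counts match a brute-force loop on seeded toy networks", {
  tab <- random_edge_table(6L, 10L, 99L)
  net <- ppi_network(tab)
  rs <- sample_random_sets(net, set_size = 3L, n_sets = 10L, seed = 7L)
  for (g in net$nodes) {
    target <- setdiff(net$nodes, g)[1:3]
    mis <- max_interaction_score(g, target, net)
    expect_equal(mis, naive_mis(g, target, tab))
    rec <- permutation_pvalue(g, mis, rs, net)
    lam <- naive_lambda(g, mis, rs$sets, tab)
    expect_equal(rec$lambda, lam)
    expect_equal(rec$p_value, lam / 10)
    expect_identical(random_set_mis(g, rs, net),
                     vapply(rs$sets, naive_mis, integer(1L), gene = g,
                            edge_table = tab))
  }
})

test_that("p-values live on the permutation grid and respect degenerate
           limits", {
  net <- toy_network()
  rs <- sample_random_sets(net, set_size = 2L, n_sets = 10L, seed = 1L)
  # the maximum possible score cannot be strictly exceeded
  expect_equal(permutation_pvalue("g", 999L, rs, net)$p_value, 0)
  # a hub with MIS 0 loses to every random set that touches a neighbour
  hub <- ppi_network(data.frame(p1 = "h", p2 = paste0("x", 1:6),
                                score = rep(500L, 6L)))
  rs_hub <- sample_random_sets(hub, set_size = 6L, n_sets = 25L, seed = 2L)
  rec <- permutation_pvalue("h", 0L, rs_hub, hub)
  expect_equal(rec$p_value, 1)
  expect_equal(rec$lambda, 25L)
})

test_that("lambda is non-increasing in the observed MIS", {
  net <- ppi_network(random_edge_table(25L, 100L, 3L))
  rs <- sample_random_sets(net, set_size = 6L, n_sets = 50L, seed = 5L)
  for (g in net$nodes[1:8]) {
    lam <- vapply(c(0L, 200L, 500L, 800L, 999L), function(m) {
      permutation_pvalue(g, m, rs, net)$lambda
    }, integer(1L))
    expect_true(all(diff(lam) <= 0L))
  }
})

test_that("class scoring composes per-gene records in catalog order and reuses
           one null", {
  net <- toy_network()
  rs <- sample_random_sets(net, set_size = 2L, n_sets = 10L, seed = 1L)
  query <- gene_set(c("a", "b"), "query")
  one <- score_disease_class(gene_set("g", "solo"), query, rs, net)
  expect_equal(nrow(one), 1L)
  expect_equal(one$mis, 700L)
  expect_equal(one,
               permutation_pvalue("g", max_interaction_score("g", query, net),
                                  rs, net))
  multi <- score_disease_class(gene_set(c("c", "g"), "cl"), query, rs, net)
  expect_equal(multi$gene, c("c", "g"))
  expect_warning(
    empty <- score_disease_class(
      structure(list(name = "void", members = character(),
                     n_duplicates = 0L), class = "gene_set"),
      query, rs, net),
    "no genes")
  expect_equal(nrow(empty), 0L)
})

test_that("a fully planted class at the top score gets p = 0 everywhere", {
  spec <- synthetic_study_spec(
    n_proteins = 120L, query_size = 15L,
    classes = data.frame(name = "planted", n_genes = 20L, strength = 1,
                         score_low = 999L, score_high = 999L),
    seed = 11L)
  st <- generate_study(spec)
  rs <- sample_random_sets(st$network, set_size = 15L, n_sets = 100L,
                           seed = 11L)
  rec <- score_disease_class(st$catalog$classes$planted, st$query_set, rs,
                             st$network)
  expect_equal(rec$p_value, rep(0, 20L))
  expect_equal(rec$mis, rep(999L, 20L))
})

test_that("scoring a random query set yields roughly uniform p-values", {
  # exchangeability: the query set is itself a uniform draw, so any gene's
  # p-value is near-uniform on the grid up to tie-induced downward bias
  net <- generate_background_network(150L, 0.15, seed = 21L)
  set.seed(22L)
  query <- gene_set(sample(net$nodes, 15L), "query")
  genes <- setdiff(net$nodes, query$members)[1:60]
  rs <- sample_random_sets(net, set_size = 15L, n_sets = 100L, seed = 23L)
  p <- score_disease_class(gene_set(genes, "null"), query, rs, net)$p_value
  expect_gt(mean(p), 0.35)
  expect_lt(mean(p), 0.6)
})

test_that("records are identical across repeated runs and gene orderings", {
  net <- ppi_network(random_edge_table(20L, 60L, 8L))
  query <- gene_set(net$nodes[1:5], "q")
  genes <- net$nodes[6:15]
  rs <- sample_random_sets(net, set_size = 5L, n_sets = 30L, seed = 9L)
  a <- score_disease_class(gene_set(genes, "c"), query, rs, net)
  b <- score_disease_class(gene_set(genes, "c"), query, rs, net)
  expect_identical(a, b)
  rev_order <- score_disease_class(gene_set(rev(genes), "c"), query, rs, net)
  expect_equal(a[order(a$gene), ], rev_order[order(rev_order$gene), ],
               ignore_attr = TRUE)
})
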