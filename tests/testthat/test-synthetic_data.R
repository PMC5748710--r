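test_that("background networks are reproducible and match the binomial edge
           budget", {
  a <- generate_background_network(200L, 0.05, seed = 61L)
  b <- generate_background_network(200L, 0.05, seed = 61L)
  expect_equal(a$edges, b$edges)
  expect_equal(length(a$nodes), 200L)   # isolated vertices stay in the universe

  # C(200,2) = 19900 pairs, mean 995, sd = sqrt(19900 * .05 * .95) ~ 30.7
  expect_lt(abs(n_edges(a) - 995), 3 * 30.75)
  expect_true(all(a$edges$score >= 150L & a$edges$score <= 999L))

  # near-saturation: every pair present
  full <- generate_background_network(5L, 0.999, seed = 62L)
  expect_equal(n_edges(full), 10L)
  expect_error(generate_background_network(10L, 1.5, seed = 1L),
               "edge_probability")
  expect_error(generate_background_network(1L, 0.5, seed = 1L), ">= 2")
})

test_that("the skewed score sampler is low-score-heavy, the uniform one
           flat", {
  set.seed(63)
  sk <- score_sampler("skewed")(5000L)
  un <- score_sampler("uniform")(5000L)
  expect_lt(median(sk), median(un))
  expect_true(all(sk >= 150L & sk <= 999L))
  expect_error(score_sampler("uniform", low = 900, high = 200), "low")
})

test_that("planting respects strength, overwrites scores, and leaves the rest
           untouched", {
  net <- generate_background_network(150L, 0.1, seed = 71L)
  cls <- gene_set(net$nodes[1:100], "cl")
  query <- gene_set(net$nodes[101:120], "q")

  expect_identical(
    plant_class_association(net, cls, query, strength = 0, seed = 1L)$edges,
    net$edges)

  planted <- plant_class_association(net, cls, query, strength = 1,
                                     score_low = 999L, score_high = 999L,
                                     seed = 72L)
  mis <- vapply(cls$members, max_interaction_score, integer(1L),
                target_set = query, network = planted)
  expect_true(all(mis == 999L))
  # untouched pairs keep their score
  untouched <- net$edges[!(net$edges$protein1 %in% cls$members |
                             net$edges$protein2 %in% cls$members) &
                           !(net$edges$protein1 %in% query$members |
                               net$edges$protein2 %in% query$members)]
  expect_equal(edge_score(planted, untouched$protein1, untouched$protein2),
               untouched$score)

  # binomial planted count at strength 1/2: mean 50, sd 5 (a score of
  # exactly 999 pre-existing in the background is vanishingly rare)
  half <- plant_class_association(net, cls, query, strength = 0.5,
                                  score_low = 999L, score_high = 999L,
                                  seed = 73L)
  mis_half <- vapply(cls$members, max_interaction_score, integer(1L),
                     target_set = query, network = half)
  expect_lt(abs(sum(mis_half == 999L) - 50), 3 * 5)
  expect_error(plant_class_association(net, cls, gene_set("zz", "q"), 0.5),
               "network nodes")
})

test_that("generated studies round-trip through the file readers
           unchanged", {
  spec <- synthetic_study_spec(
    n_proteins = 60L, edge_probability = 0.15, query_size = 8L,
    classes = data.frame(name = c("one", "two"), n_genes = c(5L, 4L),
                         strength = c(0.9, 0)),
    seed = 81L)
  st <- generate_study(spec)
  expect_equal(st$truth, c(one = 0.9, two = 0))
  expect_true(all(st$query_set$members %in% st$network$nodes))
  expect_true(all(unlist(lapply(st$catalog$classes, `[[`, "members")) %in%
                    st$network$nodes))

  dir <- tempfile()
  paths <- expect_no_warning(write_study(st, dir))
  back_net <- expect_no_warning(read_string_links(paths[["network"]]))
  expect_equal(back_net$edges, st$network$edges)
  back_q <- expect_no_warning(read_gene_set(paths[["query"]], "query"))
  expect_equal(back_q$members, st$query_set$members)
  back_cat <- expect_no_warning(read_class_catalog(paths[["catalog"]]))
  expect_equal(lapply(back_cat$classes, `[[`, "members"),
               lapply(st$catalog$classes, `[[`, "members"))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(unlist(truth), st$truth)

  # identical seed, identical study
  expect_equal(generate_study(spec)$network$edges, st$network$edges)
})

test_that("infeasible or invalid study specs are rejected", {
  expect_error(synthetic_study_spec(
    n_proteins = 20L, query_size = 10L,
    classes = data.frame(name = "a", n_genes = 15L, strength = 0)),
    "infeasible")
  expect_error(synthetic_study_spec(
    classes = data.frame(name = "a", n_genes = 5L, strength = 2)),
    "strength")
  expect_error(synthetic_study_spec(
    classes = data.frame(name = "a", n_genes = 5L, strength = 0.5,
                         score_low = 100L, score_high = 999L)),
    "within the global")
})

test_that("recovered class AUC increases with planting strength on
           average", {
  strengths <- c(0, 0.5, 1)
  auc <- matrix(NA_real_, nrow = 20L, ncol = 3L)
  for (r in 1:20) {
    spec <- synthetic_study_spec(
      n_proteins = 120L, edge_probability = 0.1, query_size = 12L,
      classes = data.frame(name = c("s0", "s5", "s10"), n_genes = 15L,
                           strength = strengths),
      seed = 100L + r)
    st <- generate_study(spec)
    assoc <- associate_classes(st$network, st$query_set, st$catalog,
                               n_permutations = 50L, seed = 200L + r)
    summ <- class_summary(assoc$results)
    auc[r, ] <- summ$auc[match(c("s0", "s5", "s10"), summ$class_name)]
  }
  means <- colMeans(auc)
  expect_true(all(diff(means) > 0))
})
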