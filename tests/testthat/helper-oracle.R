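# Independent brute-force oracles: straight double loops over the raw edge
# table, sharing no code with the package's adjacency/index implementation.

naive_mis <- function(gene, members, edge_table) {
  members <- setdiff(members, gene)
  hit <- (edge_table$p1 == gene & edge_table$p2 %in% members) |
         (edge_table$p2 == gene & edge_table$p1 %in% members)
  if (any(hit)) max(edge_table$score[hit]) else 0L
}

naive_lambda <- function(gene, query_mis, sets, edge_table) {
  sum(vapply(sets, function(d) {
    naive_mis(gene, d, edge_table) > query_mis
  }, logical(1L)))
}

# step-function integral of t -> mean(p < t) on a fine regular grid
naive_step_auc <- function(p, h = 0.001) {
  grid <- seq(0, 1, by = h)
  f <- vapply(grid, function(t) mean(p < t), numeric(1L))
  sum((f[-1L] + f[-length(f)]) / 2) * h
}

# random undirected edge table (distinct pairs, no self-loops)
random_edge_table <- function(n_nodes, n_edges, seed,
                              scores = 150:999) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2L))
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  data.frame(p1 = pairs[pick, 1L], p2 = pairs[pick, 2L],
             score = sample(scores, length(pick), replace = TRUE),
             stringsAsFactors = FALSE)
}
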