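# Shared helpers: fixture builders and graph utilities used across tests.

ig_of <- function(g) igraph::graph_from_edgelist(g$edges, directed = FALSE)

graphs_isomorphic <- function(g1, g2) {
  igraph::isomorphic(ig_of(g1), ig_of(g2), method = "vf2")
}

# single hexagonal ring (benzene skeleton)
hexagon_ring <- function() {
  build_from_adjacency(lapply(1:6, function(v) {
    sort(c(if (v == 1) 6 else v - 1, if (v == 6) 1 else v + 1))
  }), name = "hexagon")
}

single_edge_graph <- function() {
  build_from_adjacency(list(2L, 1L), name = "K2")
}

path3_graph <- function() {
  build_from_adjacency(list(2L, c(1L, 3L), 2L), name = "P3")
}

# adjacency list of g with vertices relabelled by permutation p (p[v] is the
# new label of v)
relabelled_adjacency <- function(g, p) {
  adj <- vector("list", g$n)
  for (i in seq_len(nrow(g$edges))) {
    u <- p[g$edges[i, 1]]; v <- p[g$edges[i, 2]]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  lapply(adj, sort)
}

# all isomers of C_n as graphs (wound up, named n:m)
all_isomer_graphs <- function(n) {
  lapply(generate_isomers(n), function(r) r$graph)
}

# exact vertex sum rule: integer numerators of incident orders add to the
# common denominator at every vertex
sum_rule_holds <- function(g, tab, num_col, den_col) {
  den <- tab[[den_col]][1]
  all(vapply(seq_len(g$n), function(v) {
    inc <- tab$u == v | tab$v == v
    sum(tab[[num_col]][inc]) == den
  }, TRUE))
}

toy_energy_table <- function(records, energy, unit = "kcal/mol") {
  data.frame(n = records$n, m = records$m, energy = energy,
             unit = unit, stringsAsFactors = FALSE)
}
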