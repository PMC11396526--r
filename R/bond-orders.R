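# Pauling pi bond orders from resonance-structure counts, and the linear
# bond-length models fitted over DFTB-optimized cage geometries.

#' Pauling-Kekule and Pauling-Clar pi bond orders
#'
#' In a single Kekule structure a bond is single (order 0) or double
#' (order 1); averaging over all K Kekule structures gives the classical
#' Pauling bond order pK(e) = K(G - u - v) / K(G).  In a Clar cover a bond
#' may additionally belong to an aromatic sextet (order 1/2); averaging over
#' all C Clar covers gives the Pauling-Clar order
#' pC(e) = (C(G - u - v) + 1/2 * sum_h C(G - V(h))) / C(G), the sum running
#' over candidate sextet rings h containing e.  All counts are exact
#' integers obtained from the ZZ engine on induced subgraphs with a memo
#' table shared across the edges of one call, and the orders are stored as
#' exact numerator/denominator pairs so that the per-vertex sum rules
#' (incident orders add to 1) hold without rounding.
#'
#' @param graph a `plane_graph` with at least one Kekule structure (pK) or
#'   Clar cover (pC).
#' @return a data.frame of class `bond_order_table` with one row per edge:
#'   `u`, `v`, the order column (`pK` or `pC`), exact `num`/`den` columns
#'   (pC numerators are in halves: pC = pC_num2 / pC_den2), and `hexagons`,
#'   a list-column with the candidate sextet rings through each edge.
#' @examples
#' tab <- pauling_kekule_orders(fixture_dodecahedron())
#' unique(tab$pK)  # 1/3 on every edge of the dodecahedron
#' @export
pauling_kekule_orders <- function(graph) {
  stopifnot(inherits(graph, "plane_graph"))
  n <- graph$n
  edges <- graph$edges
  full <- seq_len(n)
  masks <- c(list(full),
             lapply(seq_len(nrow(edges)), function(i) {
               setdiff(full, edges[i, ])
             }))
  res <- zz_multi_cpp(n, edges, list(), masks)  # no rings: pure K counts
  K <- .poly0(res[[1]])
  if (K == 0) stop("graph has no Kekule structure (K = 0)")
  Ke <- vapply(res[-1], .poly0, numeric(1))
  tab <- data.frame(u = edges[, 1], v = edges[, 2],
                    pK = Ke / K, pK_num = Ke, pK_den = K)
  tab$hexagons <- .edge_rings(graph)
  class(tab) <- c("bond_order_table", class(tab))
  attr(tab, "graph_name") <- graph$name
  tab
}

.poly0 <- function(co) if (length(co)) co[1] else 0

.edge_rings <- function(graph) {
  rings <- sextet_candidates(graph)
  rkeys <- lapply(rings, function(r) .edge_key(r, r[c(2:6, 1)]))
  lapply(seq_len(nrow(graph$edges)), function(i) {
    key <- .edge_key(graph$edges[i, 1], graph$edges[i, 2])
    which(vapply(rkeys, function(ks) key %in% ks, TRUE))
  })
}

#' @rdname pauling_kekule_orders
#' @export
pauling_clar_orders <- function(graph) {
  stopifnot(inherits(graph, "plane_graph"))
  n <- graph$n
  edges <- graph$edges
  rings <- sextet_candidates(graph)
  full <- seq_len(n)
  masks <- c(list(full),
             lapply(seq_len(nrow(edges)), function(i) setdiff(full, edges[i, ])),
             lapply(rings, function(r) setdiff(full, r)))
  res <- zz_multi_cpp(n, edges, rings, masks)
  Ctot <- sum(res[[1]])
  if (Ctot == 0) stop("graph has no Clar cover (C = 0)")
  ne <- nrow(edges)
  Ce <- vapply(res[1 + seq_len(ne)], sum, numeric(1))
  Ch <- vapply(res[1 + ne + seq_along(rings)], sum, numeric(1))
  er <- .edge_rings(graph)
  num2 <- vapply(seq_len(ne), function(i) {
    2 * Ce[i] + sum(Ch[er[[i]]])
  }, numeric(1))
  tab <- data.frame(u = edges[, 1], v = edges[, 2],
                    pC = num2 / (2 * Ctot), pC_num2 = num2,
                    pC_den2 = 2 * Ctot)
  tab$hexagons <- er
  class(tab) <- c("bond_order_table", class(tab))
  attr(tab, "graph_name") <- graph$name
  tab
}

#' Linear bond-length models
#'
#' Built-in linear fits length = intercept + slope * order (angstrom) relating
#' the Pauling orders to DFTB-optimized bond lengths across the full
#' C20-C70 isomer set: 1.5096 - 0.2016 x for the Clar (pC) model and
#' 1.5708 - 0.3851 x for the Kekule (pK) model.
#'
#' @param model "clar" or "kekule", or a list with `intercept` and `slope`.
#' @return a list with fields `intercept`, `slope`, `model`.
#' @export
bond_length_model <- function(model = c("clar", "kekule")) {
  if (is.list(model)) {
    stopifnot(is.numeric(model$intercept), is.numeric(model$slope))
    return(structure(list(intercept = model$intercept, slope = model$slope,
                          model = "custom"), class = "bond_length_model"))
  }
  model <- match.arg(model)
  par <- switch(model,
                clar   = c(1.5096, -0.2016),
                kekule = c(1.5708, -0.3851))
  structure(list(intercept = par[1], slope = par[2], model = model),
            class = "bond_length_model")
}

#' Predict bond lengths from pi bond orders
#'
#' @param orders numeric vector of bond orders in `[0, 1]`, or a
#'   `bond_order_table` (its `pC` or `pK` column is used according to the
#'   model).
#' @param model a [bond_length_model()] or its name.
#' @return predicted bond lengths in angstrom.
#' @examples
#' predict_bond_lengths(0, "clar")    # 1.5096, the model intercept
#' predict_bond_lengths(1, "kekule")  # 1.5708 - 0.3851 = 1.1857
#' @export
predict_bond_lengths <- function(orders, model = "clar") {
  if (!inherits(model, "bond_length_model")) model <- bond_length_model(model)
  if (inherits(orders, "bond_order_table")) {
    col <- if (identical(model$model, "kekule") && "pK" %in% names(orders)) "pK"
           else if ("pC" %in% names(orders)) "pC" else "pK"
    orders <- orders[[col]]
  }
  model$intercept + model$slope * orders
}

#' Least-squares fit of bond length on bond order
#'
#' Ordinary least squares of length (angstrom) on pi bond order, the same
#' functional form as the built-in models; R^2 is the squared sample
#' correlation.
#'
#' @param orders numeric vector of bond orders.
#' @param lengths numeric vector of bond lengths (angstrom).
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
regress_orders_vs_lengths <- function(orders, lengths) {
  stopifnot(length(orders) == length(lengths))
  if (length(orders) < 3L) stop("need at least 3 (order, length) pairs")
  if (length(unique(orders)) < 2L) {
    stop("all bond orders identical: no fit possible")
  }
  fit <- stats::lm(lengths ~ orders)
  r2 <- if (stats::sd(lengths) == 0) 1 else stats::cor(orders, lengths)^2
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n = length(orders))
}

#' Bond-order table with length predictions as TSV
#'
#' Merges the Kekule and Clar order tables of a graph and appends the
#' model-predicted lengths: columns u, v, pK, pC, len_pred_K, len_pred_C.
#'
#' @param graph a `plane_graph`.
#' @return the combined data.frame (invisibly written if `path` given).
#' @param path optional output path.
#' @export
bond_order_report <- function(graph, path = NULL) {
  tk <- pauling_kekule_orders(graph)
  tc <- pauling_clar_orders(graph)
  out <- data.frame(u = tk$u, v = tk$v, pK = tk$pK, pC = tc$pC,
                    len_pred_K = predict_bond_lengths(tk$pK, "kekule"),
                    len_pred_C = predict_bond_lengths(tc$pC, "clar"))
  if (!is.null(path)) {
    utils::write.table(format(out, digits = 10), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
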