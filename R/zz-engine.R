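# Zhang-Zhang (Clar covering) polynomials and the derived invariants:
# Kekule count K = ZZ(0), Clar count C = ZZ(1), Clar number Cl = deg ZZ,
# Clar-formula count = leading coefficient.  The production path is the
# memoized vertex-branching recursion in C++; brute-force enumeration
# oracles in plain R provide an independent check on small graphs.

#' Candidate aromatic sextet rings
#'
#' All simple 6-cycles of the graph, computed once.  A Clar-cover component
#' may be any cycle of girth six, not only a face; for (5,6)-fullerenes the
#' two notions coincide, and this is verified at run time whenever the input
#' is a fullerene cage.
#'
#' @param graph a `plane_graph`.
#' @return list of integer 6-vectors (one per 6-cycle).
#' @export
sextet_candidates <- function(graph) {
  stopifnot(inherits(graph, "plane_graph"))
  rings <- find_rings(graph$n, graph$edges, 6L)
  if (inherits(graph, "fullerene_graph")) {
    hex <- graph$faces[graph$face_kind == "hexagon"]
    hkeys <- sort(vapply(hex, function(f) paste(sort(f), collapse = ","), ""))
    rkeys <- sort(vapply(rings, function(f) paste(sort(f), collapse = ","), ""))
    if (!identical(hkeys, rkeys)) {
      stop("internal check failed: this cage has non-facial 6-cycles")
    }
  }
  rings
}

.zz_poly <- function(coeffs, name = NULL) {
  coeffs <- as.numeric(coeffs)
  structure(list(coeffs = coeffs,
                 degree = if (length(coeffs)) length(coeffs) - 1L else -1L,
                 name = name),
            class = "zz_polynomial")
}

#' Zhang-Zhang polynomial of a pentagon/hexagon plane graph
#'
#' ZZ(B, x) = sum_k c_k x^k where c_k counts the Clar covers of order k:
#' spanning subgraphs whose components are single edges (K2, double bonds)
#' or candidate 6-cycles (C6, aromatic sextets), with k sextets.  Computed
#' by a memoized vertex-branching recursion in which every state is an
#' induced subgraph keyed by its live-vertex bit set; coefficients are exact
#' integer counts.
#'
#' @param graph a `plane_graph`.
#' @param size_limit refuse graphs with more vertices than this (guards the
#'   exponential-state recursion; default 120).
#' @return an object of class `zz_polynomial` with fields `coeffs`
#'   (c0..cCl; `numeric(0)` for the zero polynomial), `degree` (the Clar
#'   number; -1 when no cover exists) and `name`.
#' @examples
#' zz(fixture_corannulene())  # 11 + 15 x + 5 x^2
#' @export
zz <- function(graph, size_limit = 120L) {
  stopifnot(inherits(graph, "plane_graph"))
  if (graph$n > size_limit) {
    stop("graph exceeds the configured size limit (", size_limit, " vertices)")
  }
  rings <- sextet_candidates(graph)
  co <- zz_multi_cpp(graph$n, graph$edges, rings, list())[[1]]
  .zz_poly(co, name = graph$name)
}

#' @export
print.zz_polynomial <- function(x, ...) {
  cat("ZZ polynomial", if (!is.null(x$name)) paste0("(", x$name, ")") else "",
      ": ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.zz_polynomial <- function(x, ...) {
  if (!length(x$coeffs)) return("0")
  k <- seq_along(x$coeffs) - 1L
  terms <- ifelse(k == 0L, format(x$coeffs, scientific = FALSE, trim = TRUE),
                  ifelse(k == 1L,
                         paste0(format(x$coeffs, scientific = FALSE, trim = TRUE), " x"),
                         paste0(format(x$coeffs, scientific = FALSE, trim = TRUE),
                                " x^", k)))
  paste(terms[x$coeffs != 0 | k == 0L], collapse = " + ")
}

#' Evaluate a ZZ polynomial
#' @param poly a `zz_polynomial`.
#' @param x evaluation point.
#' @return numeric value.
#' @export
zz_eval <- function(poly, x) {
  if (!length(poly$coeffs)) return(0)
  sum(poly$coeffs * x^(seq_along(poly$coeffs) - 1L))
}

.as_zz <- function(graph_or_poly) {
  if (inherits(graph_or_poly, "zz_polynomial")) graph_or_poly
  else zz(graph_or_poly)
}

#' Resonance-theoretic invariants from the ZZ polynomial
#'
#' `kekule_count` is K = ZZ(B, 0) (the number of perfect matchings),
#' `clar_count` is C = ZZ(B, 1) (the total number of Clar covers),
#' `clar_number` is Cl = deg ZZ(B, x) (reported as -1 with no cover), and
#' `clar_formula_count` is the leading coefficient (covers attaining Cl).
#'
#' @param graph a `plane_graph` or a precomputed `zz_polynomial`.
#' @return a single number.
#' @examples
#' kekule_count(fixture_corannulene())  # 11
#' @export
kekule_count <- function(graph) {
  p <- .as_zz(graph)
  if (!length(p$coeffs)) 0 else p$coeffs[1]
}

#' @rdname kekule_count
#' @export
clar_count <- function(graph) {
  p <- .as_zz(graph)
  sum(p$coeffs)
}

#' @rdname kekule_count
#' @export
clar_number <- function(graph) {
  .as_zz(graph)$degree
}

#' @rdname kekule_count
#' @export
clar_formula_count <- function(graph) {
  p <- .as_zz(graph)
  if (!length(p$coeffs)) 0 else p$coeffs[length(p$coeffs)]
}

#' Exhaustive Clar-cover enumeration (oracle)
#'
#' Backtracking over the lowest-index uncovered vertex, which is covered
#' either by one of its incident edges or by a candidate 6-cycle through it.
#' Complete and duplicate-free, but exponential: guarded to small graphs.
#' This is a pure-R path entirely independent of the C++ recursion, used to
#' cross-validate it.
#'
#' @param graph a `plane_graph`.
#' @param guard refuse graphs with more vertices than this.
#' @return list of covers; each cover is a list with `edges` (2-column
#'   matrix of double bonds) and `sextets` (list of 6-cycles); its order is
#'   `length(sextets)`.
#' @export
enumerate_clar_covers <- function(graph, guard = 32L) {
  stopifnot(inherits(graph, "plane_graph"))
  if (graph$n > guard) {
    stop("graph exceeds the enumeration guard (", guard, " vertices)")
  }
  n <- graph$n
  adj <- .adj_from_edges(n, graph$edges)
  rings <- find_rings(n, graph$edges, 6L)
  vrings <- lapply(seq_len(n), function(v) {
    which(vapply(rings, function(r) v %in% r, TRUE))
  })
  covers <- list()
  rec <- function(free, edges, sextets) {
    u <- which(free)[1]
    if (is.na(u)) {
      covers[[length(covers) + 1L]] <<- list(
        edges = if (length(edges)) do.call(rbind, edges)
                else matrix(integer(), 0, 2),
        sextets = sextets)
      return(invisible())
    }
    for (w in adj[[u]]) {
      if (free[w]) {
        free[c(u, w)] <- FALSE
        rec(free, c(edges, list(c(u, w))), sextets)
        free[c(u, w)] <- TRUE
      }
    }
    for (ri in vrings[[u]]) {
      r <- rings[[ri]]
      if (all(free[r])) {
        free[r] <- FALSE
        rec(free, edges, c(sextets, list(r)))
        free[r] <- TRUE
      }
    }
  }
  rec(rep(TRUE, n), list(), list())
  covers
}

#' ZZ polynomial via exhaustive enumeration (oracle)
#'
#' Histogram of Clar-cover orders from [enumerate_clar_covers()]; must agree
#' with [zz()] on every graph small enough to enumerate.
#'
#' @inheritParams enumerate_clar_covers
#' @return a `zz_polynomial`.
#' @export
zz_via_enumeration <- function(graph, guard = 32L) {
  covers <- enumerate_clar_covers(graph, guard = guard)
  if (!length(covers)) return(.zz_poly(numeric(0), name = graph$name))
  orders <- vapply(covers, function(cv) length(cv$sextets), integer(1))
  co <- tabulate(orders + 1L, nbins = max(orders) + 1L)
  .zz_poly(co, name = graph$name)
}

#' Perfect-matching count by plain edge branching (oracle)
#'
#' Independent Kekule-count oracle: M(G) = sum over edges at the first free
#' vertex of M(G - u - v), with no memoization and no sextet logic.  Agrees
#' with `zz(graph)` evaluated at 0 but shares no code with it.
#'
#' @param graph a `plane_graph`.
#' @return the number of perfect matchings.
#' @examples
#' matching_count_oracle(fixture_corannulene())  # 11
#' @export
matching_count_oracle <- function(graph) {
  stopifnot(inherits(graph, "plane_graph"))
  matching_count_cpp(graph$n, graph$edges)
}

# ---------------------------------------------------------------------------
# Invariant records

#' Per-isomer invariant records
#'
#' `invariant_record` summarizes one graph; `isomer_invariants` maps over all
#' isomers of C_n (in lexicographic spiral order) and is the work-horse
#' behind the analysis module and the `invariants` CLI subcommand.
#'
#' @param graph a `plane_graph`.
#' @param n,m isomer label (taken from the graph name "n:m" when absent).
#' @return a one-row data.frame with columns n, m, K, C, Cl, cCl and the
#'   coefficient vector packed as a space-separated string `coeffs`.
#' @export
invariant_record <- function(graph, n = NA_integer_, m = NA_integer_) {
  p <- zz(graph)
  if (is.na(n) && !is.null(graph$name) &&
      grepl("^\\d+:\\d+$", graph$name)) {
    lab <- as.integer(strsplit(graph$name, ":")[[1]])
    n <- lab[1]; m <- lab[2]
  }
  if (is.na(n)) n <- graph$n
  data.frame(n = as.integer(n), m = as.integer(m),
             K = kekule_count(p), C = clar_count(p),
             Cl = clar_number(p), cCl = clar_formula_count(p),
             coeffs = paste(format(p$coeffs, scientific = FALSE, trim = TRUE),
                            collapse = " "),
             stringsAsFactors = FALSE)
}

#' @rdname invariant_record
#' @param limit restrict to the first `limit` isomers.
#' @param progress optional function called with each completed record
#'   (used by the CLI to stream output).
#' @export
isomer_invariants <- function(n, limit = NULL, progress = NULL) {
  recs <- generate_isomers(n, limit = limit, build_graphs = FALSE)
  rows <- lapply(recs, function(r) {
    g <- windup(r$code)
    g$name <- sprintf("%d:%d", r$n, r$m)
    row <- invariant_record(g, n = r$n, m = r$m)
    if (!is.null(progress)) progress(row)
    row
  })
  do.call(rbind, rows)
}

#' Write invariant records as TSV
#'
#' Columns: n, m, K, C, Cl, cCl, coeffs (space-separated c0..cCl).
#'
#' @param records data.frame from [isomer_invariants()].
#' @param path output path ("" for stdout).
#' @export
write_invariants_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_invariants_tsv
#' @return `read_invariants_tsv` returns the records data.frame.
#' @export
read_invariants_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(coeffs = "character"))
}
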