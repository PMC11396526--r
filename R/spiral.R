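# Ring-spiral encoding of (5,6)-fullerenes: windup, canonical spiral,
# exhaustive lexicographic isomer generation and the n:m labelling.

#' Spiral codes and isomer labels
#'
#' A spiral code records the 1-based positions of the 12 pentagons in the
#' face spiral of a fullerene C_n (face count n/2 + 2).  The label `n:m`
#' denotes the m-th isomer in the lexicographic order of canonical codes.
#'
#' @param n atom count (even, >= 20).
#' @param positions strictly increasing integer 12-vector of pentagon
#'   positions in `[1, n/2 + 2]`.
#' @return an object of class `spiral_code`.
#' @examples
#' spiral_code(20, 1:12)  # the dodecahedral C20 spiral
#' @export
spiral_code <- function(n, positions) {
  n <- as.integer(n)
  positions <- as.integer(positions)
  if (n < 20L || n %% 2L != 0L) stop("n must be even and at least 20")
  if (length(positions) != 12L) stop("a spiral code has exactly 12 pentagon positions")
  if (any(diff(positions) <= 0L)) stop("pentagon positions must be strictly increasing")
  if (positions[1] < 1L || positions[12] > n / 2L + 2L) {
    stop("pentagon positions out of range [1, n/2 + 2]")
  }
  structure(list(n = n, positions = positions), class = "spiral_code")
}

#' @export
print.spiral_code <- function(x, ...) {
  cat(sprintf("spiral_code C%d: %s\n", x$n, paste(x$positions, collapse = " ")))
  invisible(x)
}

#' @export
format.spiral_code <- function(x, ...) {
  paste(c(x$n, x$positions), collapse = " ")
}

.spiral_sizes <- function(code) {
  f <- code$n %/% 2L + 2L
  s <- rep(6L, f)
  s[code$positions] <- 5L
  s
}

# Convert the dual triangulation (face adjacency matrix) produced by the
# windup into the primal cubic cage.  Fullerene graphs are cyclically
# 5-edge-connected, so every triangle of the dual is facial: the primal
# vertices are the triangles and each primal face is the link cycle of a
# dual vertex.
.dual_to_primal <- function(D) {
  f <- nrow(D)
  nb <- lapply(seq_len(f), function(a) which(D[a, ] == 1L))
  tid <- new.env(parent = emptyenv())
  ntri <- 0L
  faces <- vector("list", f)
  for (a in seq_len(f)) {
    # walk the link cycle of dual vertex a
    w0 <- nb[[a]][1]
    cyc <- integer()
    prev <- NA_integer_
    w <- w0
    repeat {
      cyc <- c(cyc, w)
      cand <- intersect(nb[[a]], nb[[w]])
      if (is.na(prev)) {
        # first step fixes the walking direction; either neighbour works
        if (length(cand) < 1L) stop("dual is not a clean triangulation")
        cand <- cand[1]
      } else {
        cand <- setdiff(cand, prev)
        if (length(cand) != 1L) stop("dual is not a clean triangulation")
      }
      prev <- w
      w <- cand
      if (w == w0) break
      if (length(cyc) > length(nb[[a]])) stop("dual link walk failed")
    }
    faces[[a]] <- vapply(seq_along(cyc), function(i) {
      b <- cyc[i]
      cc <- cyc[if (i == length(cyc)) 1L else i + 1L]
      s <- sort(c(a, b, cc))
      key <- paste(s, collapse = ",")
      id <- tid[[key]]
      if (is.null(id)) {
        ntri <<- ntri + 1L
        tid[[key]] <- ntri
        id <- ntri
      }
      id
    }, integer(1))
  }
  edges <- unique(do.call(rbind, lapply(faces, function(fc) {
    k <- length(fc)
    cbind(pmin(fc, fc[c(2:k, 1)]), pmax(fc, fc[c(2:k, 1)]))
  })))
  list(n = ntri, edges = edges, faces = faces)
}

#' Wind a spiral code up into a fullerene cage
#'
#' Faces are attached in spiral order to the open boundary; the last two
#' faces must close the cage exactly.  On failure a `windup_failure` object
#' carrying the 1-based face position of the mismatch is returned instead of
#' an error, so that enumeration loops can treat unrealizable codes cheaply.
#'
#' @param code a [spiral_code()] (or an object coercible via `spiral_code`).
#' @return a `fullerene_graph` with the spiral-induced embedding, or a
#'   `windup_failure` object with fields `code` and `fail_pos`.
#' @examples
#' g <- windup(spiral_code(20, 1:12))
#' validate_fullerene(g)$valid
#' @export
windup <- function(code) {
  stopifnot(inherits(code, "spiral_code"))
  res <- windup_cpp(.spiral_sizes(code))
  if (!res$ok) {
    return(structure(list(code = code, fail_pos = res$fail_pos),
                     class = "windup_failure"))
  }
  pr <- .dual_to_primal(res$dual)
  g <- .plane_graph_from_faces(pr$n, pr$edges, pr$faces,
                               name = sprintf("C%d spiral %s", code$n,
                                              paste(code$positions,
                                                    collapse = " ")))
  if (!inherits(g, "fullerene_graph")) stop("windup produced an invalid cage")
  attr(g, "spiral") <- code
  g
}

#' @rdname windup
#' @param x object to test.
#' @export
is_windup_failure <- function(x) inherits(x, "windup_failure")

#' @export
print.windup_failure <- function(x, ...) {
  cat(sprintf("windup failure for C%d code (%s): boundary mismatch at face %d\n",
              x$code$n, paste(x$code$positions, collapse = " "), x$fail_pos))
  invisible(x)
}

# face adjacency (dual) matrix from the stored faces of a cage
.dual_matrix <- function(graph) {
  f <- length(graph$faces)
  keys <- lapply(graph$faces, function(cyc) {
    k <- length(cyc)
    .edge_key(cyc, cyc[c(2:k, 1)])
  })
  D <- matrix(0L, f, f)
  ek <- new.env(parent = emptyenv())
  for (i in seq_len(f)) for (key in keys[[i]]) {
    j <- ek[[key]]
    if (is.null(j)) ek[[key]] <- i
    else { D[i, j] <- 1L; D[j, i] <- 1L }
  }
  D
}

#' Canonical spiral of a fullerene graph
#'
#' The lexicographically smallest pentagon-position tuple over all successful
#' face spirals of the cage (every face, boundary edge and winding direction
#' is tried).  The result is independent of vertex labelling, which makes it
#' the canonical name of the isomorphism class.
#'
#' @param graph a `fullerene_graph`.
#' @return a [spiral_code()].
#' @examples
#' canonical_spiral(fixture_dodecahedron())  # positions 1..12
#' @export
canonical_spiral <- function(graph) {
  v <- validate_fullerene(graph)
  if (!v$valid) stop("not a valid fullerene graph: ",
                     paste(v$problems, collapse = "; "))
  pos <- canonical_spiral_cpp(.dual_matrix(graph))
  spiral_code(graph$n, pos)
}

#' Generate all (5,6)-fullerene isomers of C_n
#'
#' Exhaustive depth-first search over pentagon-position prefixes with
#' incremental windup (failures prune whole subtrees); a completed spiral is
#' kept only when it equals its own canonical spiral, which deduplicates
#' isomorphism classes without storing graphs.  Isomers are returned in
#' lexicographic order with labels m = 1..count.  The ring-spiral encoding is
#' exhaustive for n <= 70; for larger cages a warning is emitted because
#' non-spiral isomers may exist in principle.
#'
#' @param n atom count (even, >= 20).
#' @param limit stop after this many isomers (NULL = all).
#' @param build_graphs if TRUE (default) each record carries the wound-up
#'   `fullerene_graph`; set FALSE to enumerate codes only.
#' @return a list of records, each with `n`, `m`, `code` and (optionally)
#'   `graph`; the count is `length()` of the result.
#' @examples
#' length(generate_isomers(24, build_graphs = FALSE))  # 1 isomer
#' @export
generate_isomers <- function(n, limit = NULL, build_graphs = TRUE) {
  n <- as.integer(n)
  if (n < 20L || n %% 2L != 0L) stop("n must be even and at least 20")
  if (n > 70L) {
    warning("the spiral algorithm is only known to be exhaustive for n <= 70; ",
            "some isomers of C", n, " may be missed")
  }
  lim <- if (is.null(limit)) -1L else as.integer(limit)
  codes <- enumerate_spirals_cpp(n, lim)
  lapply(seq_len(nrow(codes)), function(m) {
    code <- spiral_code(n, codes[m, ])
    rec <- list(n = n, m = m, code = code)
    if (build_graphs) {
      g <- windup(code)
      if (is_windup_failure(g)) stop("internal error: canonical code failed to wind")
      g$name <- sprintf("%d:%d", n, m)
      rec$graph <- g
    }
    rec
  })
}

#' Retrieve isomer n:m
#'
#' The m-th isomer of C_n in lexicographic spiral order.  Enumeration stops
#' as soon as the m-th distinct isomer has been produced.
#'
#' @param n atom count.
#' @param m 1-based rank in the lexicographic spiral order.
#' @return a `fullerene_graph` named "n:m".
#' @examples
#' g <- isomer(20, 1)  # the dodecahedron
#' @export
isomer <- function(n, m) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  recs <- generate_isomers(n, limit = m, build_graphs = FALSE)
  if (length(recs) < m) {
    stop(sprintf("C%d has only %d isomer(s); m = %d out of range",
                 n, length(recs), m))
  }
  g <- windup(recs[[m]]$code)
  g$name <- sprintf("%d:%d", n, m)
  g
}

#' Read and write spiral files
#'
#' One isomer per line: `n m p1 p2 ... p12` (all 1-based), compatible with
#' pentagon-index lists as distributed by fullerene databases.
#'
#' @param records a list as returned by [generate_isomers()].
#' @param path file path.
#' @export
write_spirals <- function(records, path) {
  lines <- vapply(records, function(r) {
    paste(c(r$n, r$m, r$code$positions), collapse = " ")
  }, "")
  writeLines(lines, path)
}

#' @rdname write_spirals
#' @return `read_spirals` returns a list of records with `n`, `m`, `code`.
#' @export
read_spirals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    x <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    if (length(x) != 14L || anyNA(x)) stop("malformed spiral file line: ", l)
    list(n = x[1], m = x[2], code = spiral_code(x[1], x[3:14]))
  })
}
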