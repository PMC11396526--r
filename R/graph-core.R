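# Plane molecular graphs with pentagon/hexagon faces: construction from
# adjacency or XYZ input, face recovery, rotation systems, validation.

.adj_from_edges <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]; v <- edges[i, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  lapply(adj, function(x) sort(unique(x)))
}

.edges_from_adj <- function(adj) {
  out <- list()
  for (u in seq_along(adj)) for (v in adj[[u]]) if (v > u)
    out[[length(out) + 1L]] <- c(u, v)
  do.call(rbind, out)
}

.edge_key <- function(u, v) paste0(pmin(u, v), "-", pmax(u, v))

.as_igraph <- function(g) {
  igraph::graph_from_edgelist(g$edges, directed = FALSE)
}

#' Find all simple cycles of given lengths
#'
#' Enumerates every simple cycle whose length is in `lengths`, each reported
#' once as an integer vector starting at its smallest vertex.  Used both for
#' face recovery (pentagon/hexagon candidates) and for sextet candidates.
#'
#' @param n number of vertices.
#' @param edges two-column integer matrix of undirected edges (1-based).
#' @param lengths cycle lengths to search for.
#' @return list of integer vectors, one per cycle.
#' @keywords internal
find_rings <- function(n, edges, lengths = c(5L, 6L)) {
  adj <- .adj_from_edges(n, edges)
  maxlen <- max(lengths)
  res <- list()
  for (s in seq_len(n)) {
    stack <- list(s)
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      last <- p[length(p)]
      for (w in adj[[last]]) {
        if (w == s && length(p) %in% lengths && p[2] < p[length(p)]) {
          res[[length(res) + 1L]] <- p
        }
        if (w > s && length(p) < maxlen && !(w %in% p)) {
          stack[[length(stack) + 1L]] <- c(p, w)
        }
      }
    }
  }
  res
}

# Trace the faces of an embedding given by a rotation system.  Arriving at v
# along (u,v), the walk departs towards the neighbour following u in the
# cyclic order at v.  Every directed edge belongs to exactly one orbit.
.trace_orbits <- function(rotation) {
  n <- length(rotation)
  succ <- vector("list", n)
  for (v in seq_len(n)) {
    rot <- rotation[[v]]
    d <- length(rot)
    s <- integer(n)
    s[rot] <- rot[c(2:d, 1)[seq_len(d)]]
    if (d == 1) s[rot] <- rot
    succ[[v]] <- s
  }
  used <- matrix(FALSE, n, n)
  faces <- list()
  for (u0 in seq_len(n)) for (v0 in rotation[[u0]]) {
    if (used[u0, v0]) next
    cyc <- integer()
    u <- u0; v <- v0
    repeat {
      used[u, v] <- TRUE
      cyc <- c(cyc, u)
      w <- succ[[v]][u]
      u <- v; v <- w
      if (u == u0 && v == v0) break
      if (length(cyc) > 2L * n) stop("inconsistent rotation system")
    }
    i <- which.min(cyc)
    faces[[length(faces) + 1L]] <- c(cyc[i:length(cyc)], cyc[seq_len(i - 1L)])
  }
  faces
}

# Build a consistently oriented rotation system from a set of face cycles.
# Faces sharing an edge must traverse it in opposite directions; the
# orientation is propagated by BFS and each vertex's cyclic neighbour order
# is then assembled from the successor constraints of its incident faces.
.rotation_from_faces <- function(n, edges, faces) {
  nf <- length(faces)
  ef <- new.env(parent = emptyenv())   # edge key -> (face, from, to) rows
  for (f in seq_len(nf)) {
    cyc <- faces[[f]]
    k <- length(cyc)
    for (i in seq_len(k)) {
      a <- cyc[i]; b <- cyc[if (i == k) 1L else i + 1L]
      key <- .edge_key(a, b)
      cur <- if (is.null(ef[[key]])) list() else ef[[key]]
      if (length(cur) >= 2L) {
        stop("an edge is shared by more than two faces: ",
             "input is not a pentagon/hexagon plane graph")
      }
      cur[[length(cur) + 1L]] <- c(f, a, b)
      ef[[key]] <- cur
    }
  }
  for (i in seq_len(nrow(edges))) {
    if (is.null(ef[[.edge_key(edges[i, 1], edges[i, 2])]])) {
      stop("edge (", edges[i, 1], ",", edges[i, 2],
           ") lies in no pentagonal or hexagonal face")
    }
  }
  # propagate orientation
  orient <- rep(NA_integer_, nf)
  orient[1] <- 1L
  queue <- 1L
  keys <- ls(ef)
  fadj <- vector("list", nf)  # face -> list of (other face, parity)
  for (key in keys) {
    rows <- ef[[key]]
    if (length(rows) == 2L) {
      f1 <- rows[[1]][1]; f2 <- rows[[2]][1]
      # same written direction => one of the two must be flipped
      parity <- if (rows[[1]][2] == rows[[2]][2]) -1L else 1L
      fadj[[f1]] <- c(fadj[[f1]], list(c(f2, parity)))
      fadj[[f2]] <- c(fadj[[f2]], list(c(f1, parity)))
    }
  }
  while (length(queue)) {
    f <- queue[1]; queue <- queue[-1]
    for (e in fadj[[f]]) {
      g <- e[1]; want <- orient[f] * e[2]
      if (is.na(orient[g])) {
        orient[g] <- want
        queue <- c(queue, g)
      } else if (orient[g] != want) {
        stop("faces cannot be oriented consistently: input is non-planar")
      }
    }
  }
  if (anyNA(orient)) stop("face structure is disconnected")
  oriented <- lapply(seq_len(nf), function(f) {
    if (orient[f] == 1L) faces[[f]] else rev(faces[[f]])
  })
  # successor constraints sigma_v(prev) = next
  adj <- .adj_from_edges(n, edges)
  succ <- lapply(seq_len(n), function(v) {
    s <- rep(NA_integer_, n); s
  })
  for (cyc in oriented) {
    k <- length(cyc)
    for (i in seq_len(k)) {
      prev <- cyc[if (i == 1L) k else i - 1L]
      v <- cyc[i]
      nxt <- cyc[if (i == k) 1L else i + 1L]
      old <- succ[[v]][prev]
      if (!is.na(old) && old != nxt) stop("conflicting face corners at vertex ", v)
      succ[[v]][prev] <- nxt
    }
  }
  rotation <- vector("list", n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    d <- length(nb)
    s <- succ[[v]][nb]
    defined <- !is.na(s)
    if (any(duplicated(s[defined]))) stop("conflicting face corners at vertex ", v)
    if (d == 2L) {
      rotation[[v]] <- nb
      next
    }
    if (sum(defined) == d) {
      rot <- nb[1]
      for (i in seq_len(d - 1L)) rot <- c(rot, succ[[v]][rot[length(rot)]])
      if (anyNA(rot) || length(unique(rot)) != d) {
        stop("face corners at vertex ", v, " do not close a cycle")
      }
      rotation[[v]] <- rot
    } else {
      # complete a partial chain into the unique cyclic order (degree 3)
      if (d != 3L) stop("cannot complete rotation at vertex ", v)
      m <- succ[[v]]
      from <- nb[defined]
      if (sum(defined) == 2L) {
        start <- setdiff(from, m[from])
        if (length(start) != 1L) stop("face corners at vertex ", v, " conflict")
        rot <- c(start, m[start], m[m[start]])
      } else if (sum(defined) == 1L) {
        rot <- c(from, m[from], setdiff(nb, c(from, m[from])))
      } else {
        rot <- nb
      }
      if (anyNA(rot) || length(unique(rot)) != 3L) {
        stop("face corners at vertex ", v, " do not close a cycle")
      }
      rotation[[v]] <- rot
    }
  }
  rotation
}

# Assemble a plane_graph from bounded faces; traces the embedding, checks
# the Euler relation and classifies faces (pentagon / hexagon / outer).
.plane_graph_from_faces <- function(n, edges, faces, coords = NULL,
                                    name = NULL) {
  edges <- .normalize_edges(edges)
  rotation <- .rotation_from_faces(n, edges, faces)
  traced <- .trace_orbits(rotation)
  nE <- nrow(edges)
  if (n - nE + length(traced) != 2L) {
    stop("Euler relation violated: traced embedding is not spherical/planar")
  }
  # match traced orbits to the supplied bounded faces
  keyof <- function(cyc) paste(sort(cyc), collapse = ",")
  supplied <- vapply(faces, keyof, "")
  kind <- character(length(traced))
  matched <- logical(length(supplied))
  for (i in seq_along(traced)) {
    k <- keyof(traced[[i]])
    j <- which(!matched & supplied == k &
                 lengths(faces) == length(traced[[i]]))
    if (length(j)) {
      matched[j[1]] <- TRUE
      kind[i] <- if (length(traced[[i]]) == 5L) "pentagon" else "hexagon"
    } else {
      kind[i] <- "outer"
    }
  }
  if (sum(kind == "outer") > 1L) {
    stop("embedding has more than one unmatched face; ",
         "input is not a pentagon/hexagon plane graph")
  }
  if (!all(matched)) stop("some supplied faces were not realized as orbits")
  g <- structure(
    list(n = n, edges = edges, rotation = rotation, faces = traced,
         face_kind = kind, coords = coords, name = name),
    class = "plane_graph")
  .maybe_fullerene(g)
}

.normalize_edges <- function(edges) {
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  storage.mode(edges) <- "integer"
  edges <- unique(edges)
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

.maybe_fullerene <- function(g) {
  v <- validate_fullerene(g)
  if (v$valid) class(g) <- c("fullerene_graph", "plane_graph")
  g
}

#' Build a plane molecular graph from an adjacency matrix or neighbor list
#'
#' Recovers the plane embedding of a pentagon/hexagon polycyclic system
#' (a fullerene cage, corannulene, a single ring, ...) from its connectivity
#' alone.  The bounded faces of such systems are exactly their simple 5- and
#' 6-cycles; these are enumerated, oriented consistently and turned into a
#' rotation system.  Inputs that cannot be embedded this way (wrong degrees,
#' faces of other sizes, non-planar graphs) are rejected.
#'
#' @param adjacency a symmetric 0/1 matrix with zero diagonal, or a list whose
#'   i-th element holds the (1-based) neighbors of vertex i.
#' @param coords optional n x 3 matrix of Cartesian coordinates (angstrom).
#' @param name optional label carried by the graph.
#' @return an object of class `plane_graph` (and `fullerene_graph` when the
#'   cage is a valid (5,6)-fullerene) with fields `n`, `edges`, `rotation`,
#'   `faces`, `face_kind`, `coords` and `name`.
#' @examples
#' g <- fixture_dodecahedron()
#' h <- build_from_adjacency(lapply(seq_len(g$n), function(v) g$rotation[[v]]))
#' length(h$faces)  # 12 pentagons
#' @export
build_from_adjacency <- function(adjacency, coords = NULL, name = NULL) {
  if (is.matrix(adjacency)) {
    if (nrow(adjacency) != ncol(adjacency)) stop("adjacency matrix not square")
    if (!isTRUE(all(adjacency == t(adjacency)))) {
      stop("adjacency matrix not symmetric")
    }
    if (any(diag(adjacency) != 0)) stop("adjacency matrix has a nonzero diagonal")
    n <- nrow(adjacency)
    adj <- lapply(seq_len(n), function(v) which(adjacency[v, ] != 0))
  } else if (is.list(adjacency)) {
    n <- length(adjacency)
    adj <- lapply(adjacency, as.integer)
    for (v in seq_len(n)) {
      if (any(adj[[v]] < 1L | adj[[v]] > n)) stop("neighbor index out of range")
      for (w in adj[[v]]) if (!(v %in% adj[[w]])) stop("neighbor list not symmetric")
    }
  } else {
    stop("adjacency must be a matrix or a neighbor list")
  }
  deg <- lengths(adj)
  if (any(!deg %in% 1:3)) {
    stop("vertex degrees must be 2 or 3 (found ",
         paste(sort(unique(deg[!deg %in% 1:3])), collapse = ","), ")")
  }
  edges <- .edges_from_adj(adj)
  if (is.null(edges)) stop("graph has no edges")
  ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(ig) < n || igraph::components(ig)$no != 1L) {
    stop("graph is disconnected")
  }
  if (nrow(edges) == n - 1L) {
    # acyclic (a lone bond, a path, ...): trivial embedding with one face
    rotation <- adj
    faces <- .trace_orbits(rotation)
    g <- structure(
      list(n = n, edges = edges, rotation = rotation, faces = faces,
           face_kind = rep("outer", length(faces)), coords = coords,
           name = name),
      class = "plane_graph")
    return(g)
  }
  if (any(deg < 2L) || (n > 3L && length(igraph::articulation_points(ig)) > 0L)) {
    stop("graph is not 2-connected")
  }
  faces <- find_rings(n, edges, c(5L, 6L))
  if (!length(faces)) {
    stop("no pentagonal or hexagonal faces found; ",
         "input is not a pentagon/hexagon plane graph")
  }
  .plane_graph_from_faces(n, edges, faces, coords = coords, name = name)
}

#' Trace the faces of a plane molecular graph
#'
#' Walks the rotation system so that every directed edge is used exactly
#' once; the orbits are the faces of the embedding (including the outer face
#' for open systems such as corannulene; closed cages follow the sphere
#' convention in which all faces are pentagons or hexagons).
#'
#' @param graph a `plane_graph`.
#' @return a list of faces; each face is a list with `vertices` (ordered
#'   cycle), `size` and `kind` ("pentagon", "hexagon" or "outer").
#' @export
trace_faces <- function(graph) {
  stopifnot(inherits(graph, "plane_graph"))
  traced <- .trace_orbits(graph$rotation)
  ndir <- sum(lengths(graph$rotation))
  if (sum(lengths(traced)) != ndir) stop("inconsistent rotation system")
  if (graph$n - nrow(graph$edges) + length(traced) != 2L) {
    stop("inconsistent rotation system: Euler relation violated")
  }
  kind <- graph$face_kind
  if (length(kind) != length(traced)) {
    kind <- ifelse(lengths(traced) == 5L, "pentagon",
                   ifelse(lengths(traced) == 6L, "hexagon", "outer"))
  }
  mapply(function(v, k) list(vertices = v, size = length(v), kind = k),
         traced, kind, SIMPLIFY = FALSE)
}

#' Validate a graph as a (5,6)-fullerene
#'
#' A (5,6)-fullerene on n atoms is cubic, 2-connected, and has exactly 12
#' pentagonal and n/2 - 10 hexagonal faces.  Rather than raising, the checks
#' are reported so that callers can inspect which constraint failed.
#'
#' @param graph a `plane_graph`.
#' @return a list with `valid`, `n`, `pentagons`, `hexagons`, `cubic`,
#'   `two_connected` and a character vector `problems`.
#' @export
validate_fullerene <- function(graph) {
  stopifnot(inherits(graph, "plane_graph"))
  deg <- lengths(graph$rotation)
  np <- sum(graph$face_kind == "pentagon")
  nh <- sum(graph$face_kind == "hexagon")
  cubic <- all(deg == 3L)
  ig <- .as_igraph(graph)
  two_conn <- igraph::components(ig)$no == 1L &&
    length(igraph::articulation_points(ig)) == 0L
  problems <- character()
  if (!cubic) problems <- c(problems, "not all vertices have degree 3")
  if (!two_conn) problems <- c(problems, "graph is not 2-connected")
  if (graph$n %% 2L != 0L) problems <- c(problems, "odd number of atoms")
  if (np != 12L) {
    problems <- c(problems, sprintf("found %d pentagons (need 12)", np))
  }
  if (any(graph$face_kind == "outer")) {
    problems <- c(problems, "graph has an outer face (not a closed cage)")
  }
  if (cubic && nh != graph$n / 2L - 10L) {
    problems <- c(problems, sprintf("found %d hexagons (need n/2-10 = %d)",
                                    nh, graph$n %/% 2L - 10L))
  }
  list(valid = length(problems) == 0L, n = graph$n, pentagons = np,
       hexagons = nh, cubic = cubic, two_connected = two_conn,
       problems = problems)
}

#' Count edges shared by two pentagonal faces
#'
#' The number of abutting pentagon pairs; zero if and only if the cage
#' satisfies the isolated pentagon rule (IPR).
#'
#' @param graph a `plane_graph`.
#' @return integer count of pentagon-pentagon edges.
#' @export
pentagon_adjacency_count <- function(graph) {
  stopifnot(inherits(graph, "plane_graph"))
  pent <- graph$faces[graph$face_kind == "pentagon"]
  keys <- unlist(lapply(pent, function(cyc) {
    k <- length(cyc)
    vapply(seq_len(k), function(i) {
      .edge_key(cyc[i], cyc[if (i == k) 1L else i + 1L])
    }, "")
  }))
  sum(table(keys) == 2L)
}

# ---------------------------------------------------------------------------
# Fixtures

#' Canonical fixture graphs
#'
#' `fixture_corannulene()` builds corannulene (C20H10, hydrogens implicit as
#' degree-2 carbons): a central pentagon fused to five hexagons, 20 carbons
#' and 25 C-C bonds.  `fixture_dodecahedron()` and
#' `fixture_truncated_icosahedron()` build the two Platonic/Archimedean
#' fullerene cages C20 and C60 (Ih) from their exact solid-geometry
#' coordinates via distance-based bond perception, scaled to 1.4 angstrom
#' bonds, so the constructions are independent of the ring-spiral machinery.
#'
#' @return a `plane_graph` (corannulene) or `fullerene_graph` (cages).
#' @export
fixture_corannulene <- function() {
  hub <- 1:5
  rim <- 5 + 1:15
  attach <- 5 + c(1, 4, 7, 10, 13)
  edges <- rbind(cbind(hub, c(hub[-1], hub[1])),
                 cbind(hub, attach),
                 cbind(rim, c(rim[-1], rim[1])))
  adj <- .adj_from_edges(20L, .normalize_edges(edges))
  build_from_adjacency(adj, name = "corannulene")
}

#' @rdname fixture_corannulene
#' @export
fixture_dodecahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  co <- rbind(
    as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
    cbind(0, c(-1, -1, 1, 1) / phi, c(-phi, phi, -phi, phi)),
    cbind(c(-1, -1, 1, 1) / phi, c(-phi, phi, -phi, phi), 0),
    cbind(c(-phi, phi, -phi, phi), 0, c(-1, -1, 1, 1) / phi))
  co <- co * 1.4 / (2 / phi)  # bond length 1.4 angstrom
  .graph_from_coords(co, bond_cutoff = 1.7, name = "dodecahedron (C20)")
}

#' @rdname fixture_corannulene
#' @export
fixture_truncated_icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  signs <- function(v) {  # all sign combinations of the nonzero entries
    nz <- which(v != 0)
    sg <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(nz))))
    out <- matrix(v, nrow(sg), 3, byrow = TRUE)
    out[, nz] <- out[, nz, drop = FALSE] * sg
    out
  }
  base <- rbind(signs(c(0, 1, 3 * phi)),
                signs(c(1, 2 + phi, 2 * phi)),
                signs(c(phi, 2, 2 * phi + 1)))
  # vertices are the even (here: cyclic) axis permutations of the base orbit
  co <- rbind(base, base[, c(2, 3, 1)], base[, c(3, 1, 2)])
  stopifnot(nrow(unique(round(co, 9))) == 60L)
  co <- co * 1.4 / 2  # edge length is 2 in these coordinates
  .graph_from_coords(co, bond_cutoff = 1.7,
                     name = "truncated icosahedron (C60 Ih)")
}

.graph_from_coords <- function(coords, bond_cutoff, name = NULL) {
  d <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  adj <- lapply(seq_len(n), function(v) which(d[v, ] < bond_cutoff & seq_len(n) != v))
  build_from_adjacency(adj, coords = coords, name = name)
}

#' Naive spherical layout of a cage graph
#'
#' Places the vertices on a sphere using the three adjacency-matrix
#' eigenvectors below the principal one, scaled so that the shortest bond is
#' `bond` angstrom.  Only intended for producing readable XYZ files and
#' round-trip tests, not physically meaningful geometries.
#'
#' @param graph a `plane_graph`.
#' @param bond target minimum bonded distance (angstrom).
#' @return an n x 3 coordinate matrix.
#' @export
spherical_layout <- function(graph, bond = 1.4) {
  n <- graph$n
  A <- matrix(0, n, n)
  A[graph$edges] <- 1
  A <- A + t(A)
  ev <- eigen(A, symmetric = TRUE)
  co <- ev$vectors[, 2:4, drop = FALSE]
  co <- co / sqrt(rowSums(co^2))
  bl <- sqrt(rowSums((co[graph$edges[, 1], ] - co[graph$edges[, 2], ])^2))
  co * bond / min(bl)
}

# ---------------------------------------------------------------------------
# File I/O

#' Read a molecular graph from an XYZ file
#'
#' Standard XYZ format: an atom-count line, a comment line, then element and
#' Cartesian coordinates (angstrom).  Bonds are perceived between carbon
#' atoms closer than `bond_cutoff`; hydrogens are ignored (degree-2 carbons
#' stand for CH positions, as in corannulene).
#'
#' @param path file path.
#' @param bond_cutoff carbon-carbon bond perception cutoff in angstrom;
#'   the default 1.70 comfortably covers the 1.37-1.48 angstrom bonds of
#'   these cages while staying below next-nearest contacts (>= 2.2).
#' @return a `plane_graph` with coordinates retained.
#' @export
read_xyz <- function(path, bond_cutoff = 1.70) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L) stop("unparsable XYZ file: too short")
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat) || length(lines) < nat + 2L) stop("unparsable XYZ file")
  rec <- strsplit(trimws(lines[3:(nat + 2L)]), "\\s+")
  if (any(lengths(rec) < 4L)) stop("unparsable XYZ file: bad atom record")
  elem <- toupper(vapply(rec, `[`, "", 1L))
  co <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
  if (anyNA(co)) stop("unparsable XYZ file: bad coordinates")
  keep <- elem != "H"
  co <- co[keep, , drop = FALSE]
  n <- nrow(co)
  d <- as.matrix(stats::dist(co))
  adj <- lapply(seq_len(n), function(v) {
    which(d[v, ] < bond_cutoff & seq_len(n) != v)
  })
  if (any(lengths(adj) == 0L) ||
      igraph::components(igraph::graph_from_edgelist(
        .edges_from_adj(adj), directed = FALSE))$no != 1L) {
    stop("bond perception gives a disconnected graph; cutoff too small?")
  }
  build_from_adjacency(adj, coords = co, name = basename(path))
}

#' Write a graph to an XYZ file
#'
#' All atoms are written as carbon; coordinates are taken from the graph or
#' generated with [spherical_layout()] when absent.
#'
#' @param graph a `plane_graph`.
#' @param path output file path.
#' @param comment second-line comment.
#' @export
write_xyz <- function(graph, path, comment = NULL) {
  co <- graph$coords
  if (is.null(co)) co <- spherical_layout(graph)
  if (is.null(comment)) comment <- if (is.null(graph$name)) "" else graph$name
  lines <- c(as.character(graph$n), comment,
             sprintf("C %.6f %.6f %.6f", co[, 1], co[, 2], co[, 3]))
  writeLines(lines, path)
}

#' Read / write the adjacency-list text format
#'
#' A header line `n <count>` followed by one line per vertex listing its
#' 1-based neighbors, whitespace-separated.  `read_graph(write_graph(g))`
#' reproduces the graph with identical vertex labels.
#'
#' @param graph a `plane_graph`.
#' @param path file path.
#' @export
write_graph <- function(graph, path) {
  lines <- c(paste("n", graph$n),
             vapply(graph$rotation, paste, "", collapse = " "))
  writeLines(lines, path)
}

#' @rdname write_graph
#' @return `read_graph` returns a `plane_graph`.
#' @export
read_graph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !grepl("^n\\s+\\d+$", lines[1])) {
    stop("malformed graph file: missing 'n <count>' header")
  }
  n <- as.integer(sub("^n\\s+", "", lines[1]))
  if (length(lines) < n + 1L) stop("malformed graph file: too few lines")
  adj <- lapply(lines[2:(n + 1L)], function(l) {
    as.integer(strsplit(trimws(l), "\\s+")[[1]])
  })
  if (anyNA(unlist(adj))) stop("malformed graph file: bad neighbor entry")
  build_from_adjacency(adj, name = basename(path))
}

#' @export
print.plane_graph <- function(x, ...) {
  kindtab <- table(factor(x$face_kind, c("pentagon", "hexagon", "outer")))
  cat(sprintf("%s: %d vertices, %d edges, faces: %d pentagons, %d hexagons%s\n",
              if (inherits(x, "fullerene_graph")) "fullerene_graph"
              else "plane_graph",
              x$n, nrow(x$edges), kindtab[["pentagon"]], kindtab[["hexagon"]],
              if (kindtab[["outer"]]) " (+ outer face)" else ""))
  if (!is.null(x$name)) cat("name:", x$name, "\n")
  invisible(x)
}
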