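#' Adjacency graphs over landmarks
#'
#' Cell contacts are approximated from nuclear positions by the Gabriel
#' graph: two landmarks are adjacent iff the open ball on their connecting
#' segment as diameter contains no third landmark.  The Gabriel graph is a
#' subgraph of the Delaunay graph and a standard proxy for membrane contact
#' when only centroids are available.
#'
#' @param nodes character vector of node labels (identity names for labeled
#'   clouds, index strings for anonymous ones).
#' @param edges two-column character matrix of unordered node pairs.
#' @return An \code{adjacency_graph}: list with \code{nodes} and a
#'   canonically ordered, deduplicated \code{edges} matrix.
#' @export
adjacency_graph <- function(nodes, edges) {
  nodes <- as.character(nodes)
  edges <- canonical_edges(edges)
  if (nrow(edges)) {
    miss <- setdiff(unique(c(edges)), nodes)
    if (length(miss))
      stop("edge endpoint(s) not among nodes: ", paste(miss, collapse = ", "))
    if (any(edges[, 1] == edges[, 2])) stop("self-edges are not allowed")
  }
  structure(list(nodes = nodes, edges = edges), class = "adjacency_graph")
}

# sort each pair, drop duplicates; always a 2-column character matrix
canonical_edges <- function(edges) {
  if (is.null(edges) || length(edges) == 0L)
    return(matrix(character(0), ncol = 2))
  edges <- matrix(as.character(edges), ncol = 2)
  a <- pmin(edges[, 1], edges[, 2])
  b <- pmax(edges[, 1], edges[, 2])
  m <- unique(cbind(a, b))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

edge_keys <- function(edges) {
  if (nrow(edges) == 0L) return(character(0))
  paste(edges[, 1], edges[, 2], sep = "\r")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Gabriel graph of a landmark cloud
#'
#' @param cloud a [landmark_cloud] with at least 2 pairwise-distinct points.
#' @return An [adjacency_graph] whose nodes are the cloud's identity names
#'   (labeled cloud) or 1-based index strings (unlabeled cloud).
#' @details The empty-ball test is strict (open ball): a witness exactly on
#'   the diametral sphere does not delete an edge, so right-angle and
#'   cocircular configurations are kept deterministically.  Exactly
#'   coincident points are a degeneracy the caller must resolve (the
#'   synthetic generator's continuous jitter makes them measure-zero).
#' @examples
#' tri <- landmark_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)))
#' nrow(gabriel_graph(tri)$edges)  # equilateral triangle keeps all 3 edges
#' @export
gabriel_graph <- function(cloud) {
  pts <- if (inherits(cloud, "landmark_cloud")) cloud$points else as.matrix(cloud)
  if (nrow(pts) < 2L) stop("gabriel_graph needs at least 2 points")
  if (anyDuplicated(pts))
    stop("duplicate points make the Gabriel graph degenerate; ",
         "perturb coincident landmarks first")
  e <- .gabriel_edges_cpp(pts)
  labs <- if (inherits(cloud, "landmark_cloud") && is_labeled(cloud))
    cloud$names else as.character(seq_len(nrow(pts)))
  adjacency_graph(labs, cbind(labs[e[, 1]], labs[e[, 2]]))
}

# n_u x n_u logical adjacency matrix of an unlabeled cloud's Gabriel graph
gabriel_adjacency_matrix <- function(points) {
  n <- nrow(points)
  e <- .gabriel_edges_cpp(points)
  adj <- matrix(FALSE, n, n)
  adj[e] <- TRUE
  adj[e[, c(2, 1), drop = FALSE]] <- TRUE
  adj
}

#' Consistent adjacencies across an ensemble
#'
#' An adjacency is consistent when it is present in every labeled dataset of
#' the ensemble; consistent adjacencies are the structural constraints a
#' correct labeling of the unlabeled data must reproduce.
#'
#' @param graphs non-empty list of [adjacency_graph]s over identity names.
#' @return An [adjacency_graph] containing exactly the intersection of the
#'   edge sets (nodes: intersection of node sets).  An edge touching an
#'   identity absent from any member cannot be consistent.
#' @export
consistent_adjacencies <- function(graphs) {
  if (length(graphs) == 0L) stop("need at least one adjacency graph")
  keys <- Reduce(intersect, lapply(graphs, function(g) edge_keys(g$edges)))
  nodes <- Reduce(intersect, lapply(graphs, function(g) g$nodes))
  edges <- if (length(keys))
    matrix(unlist(strsplit(keys, "\r", fixed = TRUE)), ncol = 2, byrow = TRUE)
  else matrix(character(0), ncol = 2)
  adjacency_graph(nodes, edges)
}

#' Adjacency consistency profile
#'
#' For every adjacency seen in at least one ensemble member, the fraction of
#' members containing it.  Frequency-1 edges are exactly the consistent
#' adjacencies; intermediate frequencies grade how stable each cell contact
#' is across embryos.
#'
#' @param graphs non-empty list of [adjacency_graph]s.
#' @return A data frame with columns \code{idA}, \code{idB},
#'   \code{frequency} (in (0, 1]), sorted by decreasing frequency then
#'   lexicographically.
#' @export
consistency_profile <- function(graphs) {
  if (length(graphs) == 0L) stop("need at least one adjacency graph")
  keys <- unlist(lapply(graphs, function(g) edge_keys(g$edges)))
  tab <- table(keys)
  parts <- matrix(unlist(strsplit(names(tab), "\r", fixed = TRUE)),
                  ncol = 2, byrow = TRUE)
  df <- data.frame(idA = parts[, 1], idB = parts[, 2],
                   frequency = as.numeric(tab) / length(graphs),
                   stringsAsFactors = FALSE)
  df[order(-df$frequency, df$idA, df$idB), , drop = FALSE]
}

#' Inconsistent landmarks within a temporal window
#'
#' Compiles the division and death events whose time lies within the
#' ensemble model's window (centered on the stage time).  The returned
#' order — all divisions before all deaths, each group sorted by subject —
#' fixes the traversal order of the greedy co-optimization.
#'
#' @param events list of [lineage_event]s.
#' @param stage_time model stage time, minutes post first cleavage.
#' @param window window width in minutes (events within \code{window/2} of
#'   the stage time are kept).
#' @return Filtered, ordered list of [lineage_event]s.
#' @export
compile_inconsistent <- function(events, stage_time, window) {
  if (window <= 0) stop("window must be positive")
  keep <- Filter(function(e) abs(e$time - stage_time) <= window / 2, events)
  kinds <- vapply(keep, function(e) e$kind, "")
  subj <- vapply(keep, function(e) e$subject, "")
  keep[order(match(kinds, c("division", "death")), subj)]
}

#' Score an assignment by missing consistent adjacencies
#'
#' Given predicted identities for the unlabeled landmarks, each consistent
#' adjacency is checked in the unlabeled Gabriel graph: it is satisfied when
#' both identities are assigned and their landmarks are adjacent, and
#' otherwise counts as one violation charged to both endpoint identities.
#' The total drives modification acceptance; the per-identity counts single
#' out individually implausible matches for iterative error correction.
#'
#' @param assignment a \code{landmark_assignment} from [lap_match()], or a
#'   character vector of identities indexed by unlabeled landmark (NA =
#'   unassigned).
#' @param consistent an [adjacency_graph] of consistent adjacencies over
#'   identity names.
#' @param unlabeled_graph an [adjacency_graph] of the unlabeled cloud (nodes
#'   are index strings), or a logical adjacency matrix.
#' @return A \code{violation_score}: list with integer \code{total} and
#'   named integer vector \code{per_identity} (zero counts omitted).
#' @export
score_assignment <- function(assignment, consistent, unlabeled_graph) {
  mapping <- if (inherits(assignment, "landmark_assignment"))
    assignment$mapping else as.character(assignment)
  adj <- if (is.matrix(unlabeled_graph) && is.logical(unlabeled_graph))
    unlabeled_graph
  else {
    n <- length(mapping)
    m <- matrix(FALSE, n, n)
    e <- unlabeled_graph$edges
    if (nrow(e)) {
      ij <- cbind(as.integer(e[, 1]), as.integer(e[, 2]))
      m[ij] <- TRUE
      m[ij[, c(2, 1), drop = FALSE]] <- TRUE
    }
    m
  }
  es <- compile_edge_struct(consistent$edges, alias = NULL)
  score_mapping(mapping, es, adj)
}

# Effective constraint set after identity remapping by modifications.
# alias: named list identity -> character vector of current-cloud names
# (possibly empty = removed).  Edges collapse to group-vs-group constraints;
# groups that intersect (merged siblings) drop out as self-edges.
compile_edge_struct <- function(edges, alias = NULL) {
  if (nrow(edges) == 0L)
    return(list(a = character(0), b = character(0), multi = list()))
  if (is.null(alias)) {
    return(list(a = edges[, 1], b = edges[, 2], multi = list()))
  }
  look <- function(id) if (is.null(alias[[id]])) id else alias[[id]]
  simple_a <- character(0); simple_b <- character(0)
  multi <- list()
  seen <- character(0)
  for (i in seq_len(nrow(edges))) {
    A <- look(edges[i, 1]); B <- look(edges[i, 2])
    if (length(A) == 0L || length(B) == 0L) next      # endpoint removed
    if (length(intersect(A, B))) next                  # collapsed to self
    key <- paste(paste(sort(A), collapse = ","),
                 paste(sort(B), collapse = ","), sep = "|")
    key2 <- paste(paste(sort(B), collapse = ","),
                  paste(sort(A), collapse = ","), sep = "|")
    if (key %in% seen || key2 %in% seen) next          # dedupe remapped edges
    seen <- c(seen, key)
    if (length(A) == 1L && length(B) == 1L) {
      simple_a <- c(simple_a, A); simple_b <- c(simple_b, B)
    } else {
      multi[[length(multi) + 1L]] <- list(a = A, b = B)
    }
  }
  list(a = simple_a, b = simple_b, multi = multi)
}

# mapping: character vector, index -> identity (NA unassigned)
# es: edge struct from compile_edge_struct; adj: logical matrix
# An identity duplicated across indices (possible once frozen votes are
# injected) satisfies an edge if ANY of its indices is adjacent.
score_mapping <- function(mapping, es, adj) {
  charges <- character(0)
  total <- 0L
  dup <- unique(mapping[duplicated(mapping) & !is.na(mapping)])
  multi <- es$multi
  a <- es$a; b <- es$b
  if (length(dup) && length(a)) {
    hit <- a %in% dup | b %in% dup
    if (any(hit)) {
      for (i in which(hit))
        multi[[length(multi) + 1L]] <- list(a = a[i], b = b[i])
      a <- a[!hit]; b <- b[!hit]
    }
  }
  if (length(a)) {
    ia <- match(a, mapping)
    ib <- match(b, mapping)
    ok <- !is.na(ia) & !is.na(ib)
    sat <- logical(length(ia))
    sat[ok] <- adj[cbind(ia[ok], ib[ok])]
    miss <- !sat
    total <- total + sum(miss)
    charges <- c(charges, a[miss], b[miss])
  }
  for (m in multi) {
    ia <- which(mapping %in% m$a)
    ib <- which(mapping %in% m$b)
    sat <- length(ia) > 0L && length(ib) > 0L &&
      any(adj[ia, ib, drop = FALSE])
    if (!sat) {
      total <- total + 1L
      charges <- c(charges, m$a, m$b)
    }
  }
  per <- if (length(charges)) {
    t <- table(charges)
    setNames(as.integer(t), names(t))
  } else setNames(integer(0), character(0))
  structure(list(total = as.integer(total), per_identity = per),
            class = "violation_score")
}
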