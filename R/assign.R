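# Forbidden pairs are encoded as this cost; anything >= half of it in the
# solution means the matching was forced through a forbidden pair.  Large
# enough to dominate any feasible total (clouds are tens of micrometres),
# small enough that dual potentials on its scale keep micrometre-level
# precision in double arithmetic.
.BIG_COST <- 1e7

new_assignment <- function(mapping, total_distance, violations = NULL,
                           forbidden = NULL) {
  structure(list(mapping = mapping, total_distance = total_distance,
                 violations = violations, forbidden = forbidden),
            class = "landmark_assignment")
}

#' @export
print.landmark_assignment <- function(x, ...) {
  cat(sprintf("<landmark_assignment> %d/%d matched, total distance %.4g",
              sum(!is.na(x$mapping)), length(x$mapping), x$total_distance))
  if (!is.null(x$violations))
    cat(sprintf(", %d violations", x$violations$total))
  cat("\n")
  invisible(x)
}

# Euclidean (or squared) cost matrix, unlabeled rows x labeled columns
assignment_cost_matrix <- function(labeled_pts, unlabeled_pts, squared = FALSE) {
  d2 <- outer(rowSums(unlabeled_pts^2), rep(1, nrow(labeled_pts))) +
    outer(rep(1, nrow(unlabeled_pts)), rowSums(labeled_pts^2)) -
    2 * tcrossprod(unlabeled_pts, labeled_pts)
  d2 <- pmax(d2, 0)
  if (squared) d2 else sqrt(d2)
}

# core solve on a prepared cost matrix (rows = unlabeled, cols = labeled
# identities).  Returns list(col_of_row, row_of_col) with 0 = unmatched, or
# the first forced forbidden pair.
solve_lap <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr <= nc) {
    sel <- .lap_solve_cpp(cost)
    row_col <- sel
  } else {
    sel <- .lap_solve_cpp(t(cost))
    row_col <- integer(nr)
    row_col[sel] <- seq_len(nc)
  }
  matched <- which(row_col > 0)
  forced <- matched[cost[cbind(matched, row_col[matched])] >= .BIG_COST / 2]
  list(row_col = row_col, forced = forced)
}

#' Linear assignment matching of landmark clouds
#'
#' Matches the unlabeled landmarks to the labeled identities by solving the
#' linear assignment problem minimizing total Euclidean distance between
#' matched pairs, with an optional set of excluded (forbidden) pairs.  When
#' the clouds differ in size the excess side is left unmatched.
#'
#' @param labeled a named [landmark_cloud], pre-aligned into the same frame
#'   as \code{unlabeled}.
#' @param unlabeled an anonymous [landmark_cloud].
#' @param forbidden two-column matrix of excluded pairs: integer unlabeled
#'   index (as character or integer) in column 1, identity name in column 2.
#'   \code{NULL} for none.
#' @param squared use squared distances (sensitivity switch), default FALSE.
#' @return A \code{landmark_assignment}: \code{mapping} is a character
#'   vector over unlabeled indices (NA = unmatched), plus
#'   \code{total_distance} and the active \code{forbidden} set.
#' @examples
#' lab <- landmark_cloud(rbind(c(0, 0, 0), c(10, 0, 0)), names = c("A", "B"))
#' unl <- landmark_cloud(rbind(c(0.1, 0, 0), c(9.9, 0, 0)))
#' lap_match(lab, unl)$mapping   # "A" "B"
#' @export
lap_match <- function(labeled, unlabeled, forbidden = NULL, squared = FALSE) {
  if (!is_labeled(labeled)) stop("labeled cloud must carry identity names")
  cost <- assignment_cost_matrix(labeled$points, unlabeled$points, squared)
  colnames(cost) <- labeled$names
  cost <- apply_forbidden(cost, forbidden)
  check_feasible(cost)
  sol <- solve_lap(cost)
  if (length(sol$forced))
    stop("no feasible assignment: landmark index ", sol$forced[1],
         " has only forbidden identities left")
  assignment_from_solution(sol, cost, labeled$names, forbidden)
}

apply_forbidden <- function(cost, forbidden) {
  if (is.null(forbidden) || NROW(forbidden) == 0L) return(cost)
  forbidden <- matrix(forbidden, ncol = 2)
  idx <- suppressWarnings(as.integer(forbidden[, 1]))
  col <- match(forbidden[, 2], colnames(cost))
  keep <- !is.na(idx) & !is.na(col) & idx >= 1 & idx <= nrow(cost)
  if (any(keep)) cost[cbind(idx[keep], col[keep])] <- .BIG_COST
  cost
}

# a row (unlabeled landmark) or column (identity) that must be matched but
# has every pair forbidden can never be assigned
check_feasible <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr <= nc) {
    bad <- which(apply(cost >= .BIG_COST / 2, 1, all))
    if (length(bad))
      stop("no feasible assignment: landmark index ", bad[1],
           " has only forbidden identities left")
  }
  if (nc <= nr) {
    bad <- which(apply(cost >= .BIG_COST / 2, 2, all))
    if (length(bad))
      stop("no feasible assignment: identity '", colnames(cost)[bad[1]],
           "' has only forbidden landmarks left")
  }
}

assignment_from_solution <- function(sol, cost, ids, forbidden) {
  mapping <- rep(NA_character_, nrow(cost))
  matched <- which(sol$row_col > 0)
  mapping[matched] <- ids[sol$row_col[matched]]
  total <- sum(cost[cbind(matched, sol$row_col[matched])])
  new_assignment(mapping, total, forbidden = forbidden)
}

#' Iterative error correction of a LAP matching
#'
#' Solves the LAP, scores the result by missing consistent adjacencies, and
#' repeatedly makes the individually worst match — the assigned identity
#' with the most missing expected adjacencies — impossible (infinite cost)
#' before re-solving.  After \code{n_iters} iterations (or as soon as a
#' zero-violation assignment appears) the assignment with the lowest total
#' violations seen is returned, ties broken by smaller total distance.
#'
#' @inheritParams lap_match
#' @param consistent an [adjacency_graph] of consistent adjacencies (or an
#'   edge struct prepared internally by the co-optimizer).
#' @param n_iters maximum number of forbid-and-resolve iterations (>= 0).
#' @param unlabeled_adj optional precomputed logical Gabriel adjacency
#'   matrix of \code{unlabeled} (computed on demand otherwise).
#' @param fixed optional named character vector of frozen assignments
#'   (names = unlabeled indices as strings) injected into the mapping before
#'   scoring; frozen indices/identities take no part in the LAP.
#' @return A \code{landmark_assignment} with \code{violations} filled in and
#'   attribute \code{"trace"}: the best-so-far violation total after each
#'   iteration (non-increasing by construction).
#' @export
lap_with_iteration <- function(labeled, unlabeled, consistent, n_iters,
                               forbidden = NULL, squared = FALSE,
                               unlabeled_adj = NULL, fixed = NULL) {
  if (is.null(unlabeled_adj))
    unlabeled_adj <- gabriel_adjacency_matrix(unlabeled$points)
  es <- if (inherits(consistent, "adjacency_graph"))
    compile_edge_struct(consistent$edges) else consistent

  full_n <- nrow(unlabeled_adj)
  fixed_idx <- if (length(fixed)) as.integer(names(fixed)) else integer(0)
  free_idx <- setdiff(seq_len(full_n), fixed_idx)
  match_ids <- if (length(fixed))
    setdiff(labeled$names, unname(fixed)) else labeled$names
  keep_cols <- match(match_ids, labeled$names)

  cost0 <- assignment_cost_matrix(
    labeled$points[keep_cols, , drop = FALSE],
    unlabeled$points[free_idx, , drop = FALSE], squared)
  colnames(cost0) <- match_ids

  inject <- function(sub_mapping) {
    mapping <- rep(NA_character_, full_n)
    mapping[free_idx] <- sub_mapping
    if (length(fixed)) mapping[fixed_idx] <- unname(fixed)
    mapping
  }
  # forbidden pairs are expressed in full-cloud indices; translate rows
  to_local <- function(fb) {
    if (is.null(fb) || NROW(fb) == 0L) return(NULL)
    fb <- matrix(fb, ncol = 2)
    cbind(match(as.integer(fb[, 1]), free_idx), fb[, 2])
  }

  forb <- if (is.null(forbidden)) matrix(character(0), ncol = 2)
  else matrix(forbidden, ncol = 2)
  warn_flag <- FALSE

  solve_once <- function() {
    cost <- apply_forbidden(cost0, to_local(forb))
    sol <- solve_lap(cost)
    if (length(sol$forced)) return(NULL)
    a <- assignment_from_solution(sol, cost, match_ids, forb)
    a$mapping <- inject(a$mapping)
    a$violations <- score_mapping(a$mapping, es, unlabeled_adj)
    a
  }

  cur <- solve_once()
  if (is.null(cur)) stop("no feasible assignment under the initial forbidden set")
  best <- cur
  trace <- best$violations$total

  iter <- 0L
  locked <- character(0)   # identities whose forbidding went infeasible
  while (iter < n_iters && cur$violations$total > 0L) {
    per <- cur$violations$per_identity
    per <- per[names(per) %in% cur$mapping]       # only assigned identities
    per <- per[!names(per) %in% unname(fixed)]    # frozen ids stay put
    per <- per[!names(per) %in% locked]
    if (!length(per) || max(per) == 0L) break
    worst_ids <- names(per)[per == max(per)]
    if (length(worst_ids) > 1L) {
      # tie-break: largest matched distance first, then lexicographic
      idxs <- match(worst_ids, cur$mapping)
      dists <- sqrt(rowSums((unlabeled$points[idxs, , drop = FALSE] -
        labeled$points[match(worst_ids, labeled$names), , drop = FALSE])^2))
      ord <- order(-dists, worst_ids)
      worst_ids <- worst_ids[ord]
    }
    worst <- worst_ids[1]
    widx <- match(worst, cur$mapping)
    forb <- rbind(forb, c(as.character(widx), worst))
    nxt <- solve_once()
    if (is.null(nxt)) {
      # infeasible: drop the offending pair, lock the identity out of
      # further forbidding, and keep correcting the others
      forb <- forb[-nrow(forb), , drop = FALSE]
      locked <- c(locked, worst)
      warn_flag <- TRUE
      next
    }
    cur <- nxt
    if (cur$violations$total < best$violations$total ||
        (cur$violations$total == best$violations$total &&
         cur$total_distance < best$total_distance))
      best <- cur
    trace <- c(trace, best$violations$total)
    iter <- iter + 1L
  }
  if (warn_flag)
    warning("error correction hit an infeasible forbidden set; ",
            "kept the last feasible assignment")
  best$forbidden <- forb
  attr(best, "trace") <- trace
  best
}
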