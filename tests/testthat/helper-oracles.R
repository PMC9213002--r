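# Independent brute-force oracles used to validate the fast implementations.

# O(n^3) Gabriel oracle: open-ball test in the squared-distance form
gabriel_oracle <- function(pts) {
  n <- nrow(pts)
  edges <- NULL
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      blocked <- FALSE
      for (w in seq_len(n)) {
        if (w == a || w == b) next
        if (sum((pts[a, ] - pts[w, ])^2) + sum((pts[b, ] - pts[w, ])^2) <
            sum((pts[a, ] - pts[b, ])^2)) {
          blocked <- TRUE
          break
        }
      }
      if (!blocked) edges <- rbind(edges, c(a, b))
    }
  }
  if (is.null(edges)) matrix(integer(0), ncol = 2) else edges
}

# exhaustive LAP oracle over all injections of the smaller side into the
# larger; returns minimum total cost (Inf entries = forbidden)
lap_oracle <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr > nc) return(lap_oracle(t(cost)))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (cols in utils::combn(nc, nr, simplify = FALSE))
    for (p in perms(cols)) {
      tot <- sum(cost[cbind(seq_len(nr), p)])
      if (tot < best) best <- tot
    }
  best
}

edge_key_set <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  edges <- matrix(as.character(edges), ncol = 2)   # consistent ordering rule
  a <- pmin(edges[, 1], edges[, 2]); b <- pmax(edges[, 1], edges[, 2])
  sort(paste(a, b))
}

random_cloud <- function(n, seed, named = FALSE) {
  set.seed(seed)
  landmark_cloud(matrix(runif(n * 3, 0, 10), ncol = 3),
                 names = if (named) sprintf("c%03d", seq_len(n)))
}
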