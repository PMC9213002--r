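consensus_result <- function(per_landmark, round = 1L, diagnostics = NULL) {
  structure(list(per_landmark = per_landmark, round = as.integer(round),
                 diagnostics = diagnostics), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  pl <- x$per_landmark
  cat(sprintf("<consensus_result> round %d: %d landmarks, %d confident (%.1f%%)\n",
              x$round, nrow(pl), sum(pl$confident),
              100 * mean(pl$confident)))
  invisible(x)
}

#' Vote identities across per-member alignments
#'
#' Each ensemble member contributes one predicted identity per unlabeled
#' landmark; the most common name wins.  A landmark is confident when the
#' winner holds at least the supermajority fraction (default 75%) of the
#' votes cast (unmatched landmarks abstain and are excluded from the
#' denominator).  Several landmarks may share a winning identity; no
#' uniqueness is enforced, as forcing unique names was found to reduce
#' accuracy.
#'
#' @param assignments non-empty list of \code{landmark_assignment}s over the
#'   same unlabeled cloud.
#' @param cfg a [run_config()] (supplies \code{supermajority}).
#' @return A \code{consensus_result}: data frame \code{per_landmark} with
#'   columns \code{index}, \code{identity} (NA when nobody voted),
#'   \code{votes_for_winner}, \code{total_votes}, \code{confident}.
#' @details Ties are broken in favor of the identity proposed by the
#'   assignment with the lowest violation total, then lexicographically.
#' @export
vote <- function(assignments, cfg = run_config()) {
  if (length(assignments) == 0L) stop("need at least one assignment to vote")
  n <- length(assignments[[1]]$mapping)
  viol <- vapply(assignments, function(a)
    if (is.null(a$violations)) Inf else as.numeric(a$violations$total), 0)
  pref <- order(viol)   # assignment quality order for tie-breaking
  votes <- vapply(assignments, function(a) {
    if (length(a$mapping) != n)
      stop("assignments cover different numbers of landmarks")
    as.character(a$mapping)
  }, character(n))
  votes <- matrix(votes, nrow = n)
  per <- lapply(seq_len(n), function(i) {
    v <- votes[i, ]
    cast <- v[!is.na(v)]
    if (!length(cast))
      return(data.frame(index = i, identity = NA_character_,
                        votes_for_winner = 0L, total_votes = 0L,
                        confident = FALSE))
    tab <- table(cast)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      first_votes <- v[pref]
      first_votes <- first_votes[first_votes %in% top]
      top <- if (length(first_votes)) first_votes[1] else sort(top)[1]
    }
    data.frame(index = i, identity = top,
               votes_for_winner = as.integer(max(tab)),
               total_votes = length(cast),
               confident = max(tab) / length(cast) >= cfg$supermajority)
  })
  consensus_result(do.call(rbind, per), round = 1L)
}

# per-member pipeline for one round: pre-align then co-optimize
align_member <- function(member, unlabeled, model, corr, cfg, fixed = NULL,
                         prefit = NULL) {
  if (is.null(prefit)) {
    pre <- prealign_fit(member, unlabeled, corr, cfg)
    warped <- apply_transform(pre, unlabeled)
    ref <- cpd_refine(warped, member, beta = cfg$cpd_beta,
                      lambda = cfg$cpd_lambda,
                      outlier_weight = cfg$cpd_outlier_weight,
                      max_iters = cfg$cpd_max_iters, tol = cfg$cpd_tol)
    warped <- apply_transform(ref, warped)
  } else {
    warped <- apply_transform(prefit, unlabeled)
  }
  co <- cooptimize_labeled(member, warped, model, cfg, fixed = fixed)
  co$warped <- warped
  co
}

#' Reiteration from confident matches
#'
#' Confident winners replace the manual landmarks: a fresh TPS is fitted
#' from them for every member, and co-optimization plus voting is repeated
#' for the uncertain landmarks only, with confident identities frozen and
#' reinserted when adjacency constraints are evaluated.  Confident entries
#' are never overwritten.
#'
#' @param unlabeled the anonymous [landmark_cloud] (original frame).
#' @param model the \code{ensemble_model}.
#' @param consensus the previous round's \code{consensus_result}.
#' @param cfg a [run_config()].
#' @return A \code{consensus_result} for the next round.  With fewer than 5
#'   confident landmarks the TPS is underdetermined, so the input is
#'   returned unchanged with a warning.
#' @export
reiterate <- function(unlabeled, model, consensus, cfg = run_config()) {
  pl <- consensus$per_landmark
  conf <- pl[pl$confident & !is.na(pl$identity), , drop = FALSE]
  if (nrow(conf) < 5L) {
    warning("fewer than 5 confident landmarks; reiteration skipped")
    return(consensus)
  }
  if (all(pl$confident)) {
    out <- consensus
    out$round <- consensus$round + 1L
    return(out)
  }
  fixed <- setNames(conf$identity, as.character(conf$index))
  members <- model$labeled_clouds
  results <- vector("list", length(members))
  for (i in seq_along(members)) {
    member <- members[[i]]
    have <- conf$identity %in% member$names
    if (sum(have) < 5L) {
      results[[i]] <- NULL
      next
    }
    src <- unlabeled$points[conf$index[have], , drop = FALSE]
    dst <- member$points[match(conf$identity[have], member$names), ,
                         drop = FALSE]
    prefit <- tps_fit(src, dst, lambda = cfg$tps_lambda)
    results[[i]] <- align_member(member, unlabeled, model, corr = NULL,
                                 cfg, fixed = fixed, prefit = prefit)
  }
  results <- Filter(Negate(is.null), results)
  if (!length(results)) {
    warning("no member retained enough confident landmarks; reiteration skipped")
    return(consensus)
  }
  new_vote <- vote(lapply(results, `[[`, "assignment"), cfg)
  out_pl <- new_vote$per_landmark
  # frozen entries keep their round-1 record
  keep <- match(conf$index, out_pl$index)
  out_pl[keep, ] <- conf
  consensus_result(out_pl, round = consensus$round + 1L,
                   diagnostics = list(members = results))
}

#' Align and name an unlabeled landmark cloud
#'
#' Full pipeline: for every ensemble member, landmark pre-fit from the
#' manual correspondence table, coherent-point-drift refinement, and greedy
#' co-optimization with iterative error correction; then a supermajority
#' vote across members, and finally \code{cfg$reiteration_rounds} rounds of
#' confident-match TPS re-alignment.  Deterministic given
#' \code{cfg$rng_seed}.
#'
#' @param unlabeled anonymous [landmark_cloud].
#' @param model \code{ensemble_model} built from labeled data.
#' @param corr a [correspondence_table()] of manual matches (>= 4 for
#'   affine, >= 5 for TPS pre-alignment).
#' @param cfg a [run_config()].
#' @return The final round's \code{consensus_result}; element
#'   \code{diagnostics} holds per-member assignments, modification logs and
#'   correction traces for every round (\code{rounds} list), for diagnostics
#'   and ablation analysis.
#' @export
align_unlabeled <- function(unlabeled, model, corr, cfg = run_config()) {
  set.seed(cfg$rng_seed)
  members <- model$labeled_clouds
  results <- lapply(members, function(member)
    align_member(member, unlabeled, model, corr, cfg))
  consensus <- vote(lapply(results, `[[`, "assignment"), cfg)
  rounds <- list(list(consensus = consensus, members = results))
  r <- 0L
  while (r < cfg$reiteration_rounds) {
    nxt <- reiterate(unlabeled, model, consensus, cfg)
    if (nxt$round == consensus$round) break      # skipped: nothing to redo
    rounds[[length(rounds) + 1L]] <-
      list(consensus = nxt, members = nxt$diagnostics$members)
    consensus <- nxt
    r <- r + 1L
  }
  consensus$diagnostics <- list(rounds = rounds)
  consensus
}
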