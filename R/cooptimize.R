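#' Modification hypotheses for inconsistent landmarks
#'
#' Heterochrony between the labeled ensemble and the unlabeled sample is
#' expressed as three edits of a labeled cloud: a cell programmed to die may
#' already be gone in the sample (\code{remove_death}); a division observed
#' in the labeled data may not have happened yet (\code{merge_daughters},
#' replacing the sisters with the parent at their midpoint); or a division
#' still pending in the labeled data may have already happened
#' (\code{split_parent}, replacing the parent with two daughters sharing
#' its exact position — no division-axis prior is used).
#'
#' @param kind one of \code{"remove_death"}, \code{"merge_daughters"},
#'   \code{"split_parent"}.
#' @param event the [lineage_event] the hypothesis derives from.
#' @return A \code{modification} object.
#' @export
modification <- function(kind, event) {
  kind <- match.arg(kind, c("remove_death", "merge_daughters", "split_parent"))
  if (kind == "remove_death" && event$kind != "death")
    stop("remove_death requires a death event")
  if (kind != "remove_death" && event$kind != "division")
    stop(kind, " requires a division event")
  structure(list(kind = kind, event = event), class = "modification")
}

#' Apply a modification to a labeled cloud
#'
#' @param cloud a named [landmark_cloud].
#' @param m a [modification].
#' @return The edited [landmark_cloud].
#' @examples
#' cl <- landmark_cloud(rbind(c(1, 0, 0), c(3, 0, 0), c(0, 5, 0)),
#'                      names = c("Pa", "Pp", "Q"))
#' ev <- lineage_event("division", "P", c("Pa", "Pp"), time = 10)
#' merged <- apply_modification(cl, modification("merge_daughters", ev))
#' merged$points[merged$names == "P", ]  # midpoint (2, 0, 0)
#' @export
apply_modification <- function(cloud, m) {
  nm <- cloud$names
  ev <- m$event
  need <- switch(m$kind,
                 remove_death = ev$subject,
                 merge_daughters = ev$daughters,
                 split_parent = ev$subject)
  miss <- setdiff(need, nm)
  if (length(miss))
    stop(m$kind, " requires landmark(s) not in the cloud: ",
         paste(miss, collapse = ", "))
  pts <- cloud$points
  if (m$kind == "remove_death") {
    keep <- nm != ev$subject
    pts <- pts[keep, , drop = FALSE]; nm <- nm[keep]
  } else if (m$kind == "merge_daughters") {
    i1 <- match(ev$daughters[1], nm); i2 <- match(ev$daughters[2], nm)
    mid <- (pts[i1, ] + pts[i2, ]) / 2
    keep <- !(nm %in% ev$daughters)
    pts <- rbind(pts[keep, , drop = FALSE], mid)
    nm <- c(nm[keep], ev$subject)
  } else {                                    # split_parent
    ip <- match(ev$subject, nm)
    clash <- intersect(ev$daughters, nm)
    if (length(clash))
      stop("split_parent daughter name(s) already present: ",
           paste(clash, collapse = ", "))
    pos <- pts[ip, ]
    keep <- nm != ev$subject
    pts <- rbind(pts[keep, , drop = FALSE], pos, pos)
    nm <- c(nm[keep], ev$daughters)
  }
  landmark_cloud(pts, names = nm, time = cloud$time,
                 stage_label = cloud$stage_label, source_id = cloud$source_id)
}

# update the identity alias map (original name -> current cloud names) when
# a modification is accepted; constraint edges are rescored through it
update_alias <- function(alias, m) {
  ev <- m$event
  point_to <- function(targets, repl) {
    for (nm in names(alias))
      if (any(alias[[nm]] %in% targets))
        alias[[nm]] <- unique(c(setdiff(alias[[nm]], targets), repl))
    alias
  }
  ensure <- function(ids) {
    for (id in ids) if (is.null(alias[[id]])) alias[[id]] <- id
    alias
  }
  switch(m$kind,
    remove_death = {
      alias <- ensure(ev$subject)
      point_to(ev$subject, character(0))
    },
    merge_daughters = {
      alias <- ensure(ev$daughters)
      point_to(ev$daughters, ev$subject)
    },
    split_parent = {
      alias <- ensure(ev$subject)
      point_to(ev$subject, ev$daughters)
    })
}

#' Greedy co-optimization of a labeled cloud against unlabeled data
#'
#' Starting from the unmodified labeled cloud, every hypothesis derived
#' from the model's inconsistent-landmark list is tried in deterministic
#' order (divisions first, then deaths): the modification is applied, the
#' cloud is re-matched by LAP with iterative error correction
#' (\code{correction_iters_inner} steps), and the change is kept iff it
#' reduces total adjacency violations by at least
#' \code{cfg$accept_threshold}.  Accepted changes accumulate.  After the
#' sweep a final correction run of \code{correction_iters_final} steps
#' produces the member's best alignment.
#'
#' @param labeled one named ensemble-member [landmark_cloud].
#' @param unlabeled the unlabeled [landmark_cloud], already pre-aligned into
#'   the labeled frame.
#' @param model an \code{ensemble_model} (supplies consistent adjacencies
#'   and inconsistent events).
#' @param cfg a [run_config()].
#' @param fixed optional frozen assignments (reiteration round), as in
#'   [lap_with_iteration()].
#' @return List with \code{cloud} (the modified labeled cloud),
#'   \code{assignment} (the best \code{landmark_assignment}),
#'   \code{modifications} (data frame log: kind, subject,
#'   delta_violations, accepted), and \code{traces} (best-so-far violation
#'   totals of every correction run, for monotonicity diagnostics).
#' @export
cooptimize_labeled <- function(labeled, unlabeled, model, cfg = run_config(),
                               fixed = NULL) {
  unlabeled_adj <- gabriel_adjacency_matrix(unlabeled$points)
  edges <- model$consistent_edges$edges
  alias <- list()
  traces <- list()
  frozen_ids <- unname(fixed)

  run_correction <- function(cloud, n_iters) {
    es <- compile_edge_struct(edges, if (length(alias)) alias else NULL)
    a <- lap_with_iteration(cloud, unlabeled, es, n_iters,
                            squared = isTRUE(cfg$squared_distance),
                            unlabeled_adj = unlabeled_adj, fixed = fixed)
    traces[[length(traces) + 1L]] <<- attr(a, "trace")
    a
  }

  cur_cloud <- labeled
  best <- run_correction(cur_cloud, cfg$correction_iters_inner)
  mods <- list()

  if (is.finite(cfg$accept_threshold)) {
    for (ev in model$inconsistent) {
      hyps <- if (ev$kind == "division") {
        c(if (all(ev$daughters %in% cur_cloud$names)) "merge_daughters",
          if (ev$subject %in% cur_cloud$names) "split_parent")
      } else {
        if (ev$subject %in% cur_cloud$names) "remove_death"
      }
      # skip hypotheses touching identities frozen by a previous round
      if (length(frozen_ids)) {
        touches <- c(ev$subject, ev$daughters)
        if (any(touches %in% frozen_ids)) hyps <- NULL
      }
      accepted_for_event <- FALSE
      for (h in hyps) {
        if (accepted_for_event) break   # merge accepted => skip split
        m <- modification(h, ev)
        cand_cloud <- apply_modification(cur_cloud, m)
        cand_alias <- update_alias(alias, m)
        old_alias <- alias
        alias <- cand_alias
        cand <- run_correction(cand_cloud, cfg$correction_iters_inner)
        delta <- best$violations$total - cand$violations$total
        accept <- delta >= cfg$accept_threshold
        mods[[length(mods) + 1L]] <- data.frame(
          kind = h, subject = ev$subject, delta_violations = delta,
          accepted = accept)
        if (accept) {
          cur_cloud <- cand_cloud
          best <- cand
          accepted_for_event <- TRUE
        } else {
          alias <- old_alias
        }
      }
    }
  }

  final <- run_correction(cur_cloud, cfg$correction_iters_final)
  if (final$violations$total < best$violations$total ||
      (final$violations$total == best$violations$total &&
       final$total_distance <= best$total_distance))
    best <- final

  list(cloud = cur_cloud, assignment = best,
       modifications = if (length(mods)) do.call(rbind, mods) else
         data.frame(kind = character(0), subject = character(0),
                    delta_violations = integer(0), accepted = logical(0)),
       traces = traces)
}
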