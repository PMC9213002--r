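#' Build an ensemble anatomy model
#'
#' Summarizes several labeled clouds of the same developmental stage as (i)
#' the clouds themselves, (ii) the adjacencies consistent across all of
#' them, and (iii) the list of inconsistent landmarks — cells whose
#' division or death falls within the model's temporal window and whose
#' presence therefore varies between samples.
#'
#' @param labeled_clouds non-empty list of named [landmark_cloud]s.
#' @param events list of [lineage_event]s (the full lineage table; filtered
#'   here to the window).
#' @param stage_time stage time in minutes post first cleavage.
#' @param window_minutes temporal window width (default 13).
#' @param stage_label free-form stage name.
#' @return An \code{ensemble_model} with elements \code{labeled_clouds},
#'   \code{graphs} (per-member Gabriel graphs), \code{consistent_edges},
#'   \code{profile} (adjacency frequency table), \code{inconsistent},
#'   \code{stage_time}, \code{stage_label}, \code{window_minutes}.
#' @export
build_ensemble_model <- function(labeled_clouds, events = list(),
                                 stage_time = 0, window_minutes = 13,
                                 stage_label = "") {
  if (length(labeled_clouds) == 0L) stop("need at least one labeled cloud")
  for (cl in labeled_clouds)
    if (!is_labeled(cl))
      stop("all ensemble members must be named clouds (offender: '",
           cl$source_id, "')")
  graphs <- lapply(labeled_clouds, gabriel_graph)
  structure(list(
    labeled_clouds = labeled_clouds,
    graphs = graphs,
    consistent_edges = consistent_adjacencies(graphs),
    profile = consistency_profile(graphs),
    inconsistent = compile_inconsistent(events, stage_time, window_minutes),
    stage_time = stage_time, stage_label = stage_label,
    window_minutes = window_minutes), class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf(
    "<ensemble_model> %d members, %d consistent adjacencies, %d inconsistent landmark events\n",
    length(x$labeled_clouds), nrow(x$consistent_edges$edges),
    length(x$inconsistent)))
  invisible(x)
}

#' Serialize / load an ensemble model
#'
#' Plain-text on-disk form: one CSV per member cloud, a consistency-profile
#' CSV, a lineage CSV of the inconsistent events, and a YAML index.
#'
#' @param model an \code{ensemble_model}.
#' @param dir directory to create/use.
#' @export
write_ensemble_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  member_files <- sprintf("member_%02d.csv", seq_along(model$labeled_clouds))
  for (i in seq_along(model$labeled_clouds))
    write_cloud(model$labeled_clouds[[i]], file.path(dir, member_files[i]))
  write_csv_precise(model$profile, file.path(dir, "consistency_profile.csv"))
  write_lineage(model$inconsistent, file.path(dir, "inconsistent.csv"))
  yaml::write_yaml(list(members = member_files,
                        stage_time = model$stage_time,
                        stage_label = model$stage_label,
                        window_minutes = model$window_minutes),
                   file.path(dir, "model.yaml"))
  invisible(dir)
}

#' @rdname write_ensemble_model
#' @export
read_ensemble_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  clouds <- lapply(meta$members, function(f) read_cloud(file.path(dir, f)))
  ev_path <- file.path(dir, "inconsistent.csv")
  events <- if (file.exists(ev_path)) read_lineage(ev_path) else list()
  build_ensemble_model(clouds, events, stage_time = meta$stage_time,
                       window_minutes = meta$window_minutes,
                       stage_label = meta$stage_label)
}
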