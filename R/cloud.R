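#' Landmark clouds
#'
#' A landmark cloud is the universal currency of the pipeline: a set of 3D
#' nuclear centroids in micrometres, optionally carrying identity names
#' (labeled data) and a time stamp in minutes post first cleavage.
#'
#' @param points numeric matrix with 3 columns (x, y, z), one row per
#'   landmark.  All coordinates must be finite.
#' @param names optional character vector of identity names, one per point.
#'   Must be unique (co-located duplicates created by a split-parent
#'   modification carry distinct suffixed names, so uniqueness always holds).
#' @param time optional scalar time in minutes post first cleavage.
#' @param stage_label free-form stage description (e.g. \code{"bean"}).
#' @param source_id free-form identifier of the originating dataset.
#' @return An object of class \code{landmark_cloud}: a list with elements
#'   \code{points}, \code{names} (or \code{NULL}), \code{time},
#'   \code{stage_label}, \code{source_id}.
#' @examples
#' cl <- landmark_cloud(matrix(rnorm(30), ncol = 3),
#'                      names = sprintf("c%04d", 1:10))
#' n_landmarks(cl)
#' @export
landmark_cloud <- function(points, names = NULL, time = NULL,
                           stage_label = "", source_id = "") {
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("landmark positions must have exactly 3 columns (x, y, z), got ",
         ncol(points))
  storage.mode(points) <- "double"
  if (!all(is.finite(points)))
    stop("all landmark positions must be finite")
  if (!is.null(names)) {
    names <- as.character(names)
    if (length(names) != nrow(points))
      stop("names length (", length(names), ") does not match point count (",
           nrow(points), ")")
    if (anyDuplicated(names))
      stop("duplicate identity names in cloud: ",
           paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, names = names, time = time,
                 stage_label = stage_label, source_id = source_id),
            class = "landmark_cloud")
}

#' @rdname landmark_cloud
#' @param cloud a \code{landmark_cloud}.
#' @export
n_landmarks <- function(cloud) nrow(cloud$points)

#' @rdname landmark_cloud
#' @export
is_labeled <- function(cloud) !is.null(cloud$names)

#' @export
print.landmark_cloud <- function(x, ...) {
  cat(sprintf("<landmark_cloud> %d points, %s", n_landmarks(x),
              if (is_labeled(x)) "named" else "unlabeled"))
  if (!is.null(x$time)) cat(sprintf(", t = %g min", x$time))
  if (nzchar(x$stage_label)) cat(", stage ", x$stage_label, sep = "")
  cat("\n")
  invisible(x)
}

# maximum pairwise extent, used to express jitter/warp scales as fractions
cloud_diameter <- function(points) {
  if (is.list(points)) points <- points$points
  rng <- apply(points, 2, range)
  # max pairwise distance is bounded below by the bbox diagonal / sqrt(3);
  # for our purposes the exact max over pairs is cheap enough at n <= 1000
  if (nrow(points) <= 1000L) return(max(dist(points)))
  sqrt(sum((rng[2, ] - rng[1, ])^2))
}

#' Read a landmark cloud from CSV
#'
#' Expects columns \code{x,y,z}; optional \code{name} and \code{time}
#' columns.  Row order is preserved as index order, so an anonymous cloud's
#' landmark indices are its CSV row numbers.
#'
#' @param path path to a CSV file.
#' @param stage_label,source_id metadata attached to the returned cloud;
#'   \code{source_id} defaults to the file name.
#' @return A [landmark_cloud].
#' @export
read_cloud <- function(path, stage_label = "", source_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("x", "y", "z"))
    if (!col %in% names(df))
      stop("cloud CSV ", path, " is missing required column '", col, "'")
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at data row ", bad[1],
           " of ", path)
    if (anyNA(v))
      stop("missing value in column '", col, "' at data row ",
           which(is.na(v))[1], " of ", path)
    df[[col]] <- v
  }
  tm <- if ("time" %in% names(df)) as.numeric(df$time[1]) else NULL
  landmark_cloud(as.matrix(df[, c("x", "y", "z")]),
                 names = if ("name" %in% names(df)) df$name else NULL,
                 time = tm, stage_label = stage_label, source_id = source_id)
}

#' Write a landmark cloud to CSV
#'
#' Inverse of [read_cloud()]; positions are written with full double
#' precision so a read/write round trip preserves them to at least 9
#' significant digits.
#'
#' @param cloud a [landmark_cloud].
#' @param path output path.
#' @export
write_cloud <- function(cloud, path) {
  df <- as.data.frame(cloud$points)
  if (is_labeled(cloud)) df <- cbind(name = cloud$names, df)
  if (!is.null(cloud$time)) df$time <- cloud$time
  write_csv_precise(df, path)
}

# write.csv with enough digits for lossless double round trips
write_csv_precise <- function(df, path) {
  for (i in seq_along(df))
    if (is.double(df[[i]])) df[[i]] <- sprintf("%.17g", df[[i]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Lineage event tables
#'
#' Division and death events drive the inconsistent-landmark list: a cell
#' whose division or death falls within the temporal window of an ensemble
#' model may be present in some datasets and absent (or replaced by its
#' daughters) in others.
#'
#' @param kind \code{"division"} or \code{"death"}.
#' @param subject identity of the dividing (parent) or dying cell.
#' @param daughters character vector of exactly two distinct daughter names
#'   (divisions only).
#' @param time event time, minutes post first cleavage.
#' @return A \code{lineage_event} object.
#' @export
lineage_event <- function(kind, subject, daughters = NULL, time) {
  kind <- match.arg(kind, c("division", "death"))
  if (kind == "division") {
    if (length(daughters) != 2L || anyDuplicated(daughters))
      stop("a division must have exactly two distinct daughters (subject ",
           subject, ")")
  } else if (!is.null(daughters) && length(daughters) > 0L) {
    stop("a death has no daughters (subject ", subject, ")")
  }
  structure(list(kind = kind, subject = as.character(subject),
                 daughters = as.character(daughters), time = as.numeric(time)),
            class = "lineage_event")
}

#' @rdname lineage_event
#' @param path path to a lineage CSV with columns
#'   \code{kind,subject,daughter1,daughter2,time} (daughter columns empty for
#'   deaths).
#' @export
read_lineage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    d <- if (identical(df$kind[i], "division"))
      c(df$daughter1[i], df$daughter2[i]) else NULL
    lineage_event(df$kind[i], df$subject[i], d, df$time[i])
  })
}

#' @rdname lineage_event
#' @param events list of \code{lineage_event}s to serialize.
#' @export
write_lineage <- function(events, path) {
  df <- do.call(rbind, lapply(events, function(e) {
    data.frame(kind = e$kind, subject = e$subject,
               daughter1 = if (length(e$daughters)) e$daughters[1] else "",
               daughter2 = if (length(e$daughters)) e$daughters[2] else "",
               time = e$time)
  }))
  write_csv_precise(df, path)
}

#' Manual correspondence tables
#'
#' A handful of landmarks identified by eye in the unlabeled data seed the
#' initial affine or TPS pre-alignment.  At least 4 pairs are needed for an
#' affine fit and at least 5 non-coplanar pairs are recommended for TPS.
#'
#' @param identity character vector of labeled identity names.
#' @param index integer vector of unlabeled landmark indices (1-based CSV
#'   row order).
#' @return A data frame of class \code{correspondence_table} with columns
#'   \code{identity} and \code{index}.
#' @export
correspondence_table <- function(identity, index) {
  identity <- as.character(identity)
  index <- as.integer(index)
  if (length(identity) != length(index))
    stop("identity and index must have equal length")
  if (anyDuplicated(identity) || anyDuplicated(index))
    stop("correspondence table must not repeat an identity or an index")
  structure(data.frame(identity = identity, index = index,
                       stringsAsFactors = FALSE),
            class = c("correspondence_table", "data.frame"))
}

#' @rdname correspondence_table
#' @param path CSV with columns \code{identity,index}.
#' @export
read_correspondence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  correspondence_table(df$identity, df$index)
}

#' @rdname correspondence_table
#' @param tab a \code{correspondence_table}.
#' @export
write_correspondence <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
}

#' Write or read a consensus result
#'
#' The on-disk form is one row per unlabeled landmark with its position,
#' winning identity (empty string when no vote was cast), vote tallies and
#' confidence flag.  A write/read round trip preserves tallies exactly.
#'
#' @param result a \code{consensus_result} from [vote()] or
#'   [align_unlabeled()].
#' @param cloud the unlabeled [landmark_cloud] the result refers to.
#' @param path output CSV path.
#' @export
write_assignment <- function(result, cloud, path) {
  stopifnot(inherits(result, "consensus_result"))
  pl <- result$per_landmark
  df <- data.frame(index = pl$index,
                   x = cloud$points[pl$index, 1],
                   y = cloud$points[pl$index, 2],
                   z = cloud$points[pl$index, 3],
                   identity = ifelse(is.na(pl$identity), "", pl$identity),
                   votes_for_winner = pl$votes_for_winner,
                   total_votes = pl$total_votes,
                   confident = tolower(as.character(pl$confident)))
  write_csv_precise(df, path)
}

#' @rdname write_assignment
#' @export
read_assignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = list(identity = "character"))
  df$identity[is.na(df$identity)] <- ""
  consensus_result(data.frame(
    index = as.integer(df$index),
    identity = ifelse(df$identity == "", NA_character_, df$identity),
    votes_for_winner = as.integer(df$votes_for_winner),
    total_votes = as.integer(df$total_votes),
    confident = df$confident == "true",
    stringsAsFactors = FALSE), round = NA_integer_)
}
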