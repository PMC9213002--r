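#' Synthetic embryo specification
#'
#' Parameters of the synthetic-data generator, which emulates the
#' statistical structure the alignment algorithm assumes: embryo-shaped
#' clouds of named nuclei, per-sample positional jitter, a smooth nonlinear
#' deformation per sample, cross-modality anisotropic distortion, and a set
#' of inconsistent landmarks realized differently in every sample through
#' division and death events.
#'
#' @param n_landmarks number of nuclei in the reference cloud (default 150).
#' @param n_members labeled ensemble members to draw (default 3, matching
#'   the three labeled embryos per stage used for the real models).
#' @param jitter_sigma per-axis positional noise, as a fraction of the cloud
#'   diameter (default 0.02).
#' @param warp_amplitude amplitude of the smooth per-sample deformation as a
#'   fraction of diameter (default 0.03).
#' @param warp_smoothness length scale of the deformation as a fraction of
#'   diameter (default 0.35; larger = smoother).
#' @param frac_inconsistent fraction of cells designated as inconsistent
#'   landmarks (default 0.05, emulating the ~5% of cells with divisions or
#'   deaths inside the temporal window).
#' @param division_fraction_of_events fraction of designated events that are
#'   divisions rather than deaths (default 0.5).
#' @param anisotropy 3-vector of axis scalings applied to the unlabeled
#'   sample as the modality distortion (default \code{c(1, 1, 0.8)}).
#' @param clock_sd standard deviation (minutes) of the per-sample
#'   developmental clock offset that drives heterochrony: a designated
#'   event is realized in a sample iff its time has passed that sample's
#'   clock, so samples disagree exactly on events close to the stage time
#'   (default 3).
#' @param rng_seed integer seed; all generator randomness flows from it.
#' @return A validated \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n_landmarks = 150L, n_members = 3L,
                           jitter_sigma = 0.02, warp_amplitude = 0.03,
                           warp_smoothness = 0.35, frac_inconsistent = 0.05,
                           division_fraction_of_events = 0.5,
                           anisotropy = c(1, 1, 0.8), clock_sd = 3,
                           rng_seed = 1L) {
  spec <- list(n_landmarks = as.integer(n_landmarks),
               n_members = as.integer(n_members),
               jitter_sigma = jitter_sigma, warp_amplitude = warp_amplitude,
               warp_smoothness = warp_smoothness,
               frac_inconsistent = frac_inconsistent,
               division_fraction_of_events = division_fraction_of_events,
               anisotropy = as.numeric(anisotropy), clock_sd = clock_sd,
               rng_seed = as.integer(rng_seed))
  stopifnot(spec$n_members >= 1L, spec$n_landmarks >= 4L,
            length(spec$anisotropy) == 3L)
  if (spec$jitter_sigma < 0 || spec$jitter_sigma > 0.2)
    stop("jitter_sigma must lie in [0, 0.2]")
  if (spec$warp_amplitude < 0 || spec$warp_amplitude > 0.2)
    stop("warp_amplitude must lie in [0, 0.2]")
  if (spec$frac_inconsistent < 0 || spec$frac_inconsistent > 0.2)
    stop("frac_inconsistent must lie in [0, 0.2]")
  structure(spec, class = "synthetic_spec")
}

# ellipsoid semi-axes in micrometres (2:1:1, ~50 um long axis: bean-ish)
.ELLIPSOID <- c(25, 12.5, 12.5)

#' Reference embryo cloud
#'
#' Draws \code{n_landmarks} points quasi-uniformly inside a 2:1:1 ellipsoid
#' (50 x 25 x 25 um, an idealized embryo) by dart throwing with a minimum
#' pairwise separation of 0.3x the expected mean nearest-neighbor distance
#' at that density.  Deterministic in \code{spec$rng_seed}; names are
#' \code{c0001, c0002, ...}.
#'
#' @param spec a [synthetic_spec()].
#' @return A named [landmark_cloud].
#' @export
make_reference <- function(spec) {
  set.seed(spec$rng_seed)
  n <- spec$n_landmarks
  ax <- .ELLIPSOID
  vol <- 4 / 3 * pi * prod(ax)
  # mean NN distance of a Poisson process at density n/vol
  d_min <- 0.3 * gamma(4 / 3) * (3 * vol / (4 * pi * n))^(1 / 3)
  pts <- matrix(NA_real_, n, 3)
  accepted <- 0L
  attempts <- 0L
  while (accepted < n) {
    attempts <- attempts + 1L
    if (attempts > 500L * n)
      stop("cannot place ", n, " points at the requested minimum separation")
    cand <- runif(3, -1, 1) * ax
    if (sum((cand / ax)^2) > 1) next
    if (accepted > 0L) {
      d2 <- rowSums(sweep(pts[seq_len(accepted), , drop = FALSE], 2, cand)^2)
      if (min(d2) < d_min^2) next
    }
    accepted <- accepted + 1L
    pts[accepted, ] <- cand
  }
  landmark_cloud(pts, names = sprintf("c%04d", seq_len(n)),
                 time = 0, stage_label = "synthetic",
                 source_id = sprintf("reference_seed%d", spec$rng_seed))
}

# designate which cells carry division/death events; times fall inside a
# 13-min window centered on stage time 0, so compile_inconsistent keeps all
designate_events <- function(reference, spec) {
  set.seed(spec$rng_seed + 1000L)
  n_ev <- round(spec$frac_inconsistent * spec$n_landmarks)
  if (n_ev == 0L) return(list())
  subjects <- sample(reference$names, n_ev)
  n_div <- round(spec$division_fraction_of_events * n_ev)
  kinds <- c(rep("division", n_div), rep("death", n_ev - n_div))
  times <- runif(n_ev, -6, 6)
  lapply(seq_len(n_ev), function(i)
    lineage_event(kinds[i], subjects[i],
                  daughters = if (kinds[i] == "division")
                    paste0(subjects[i], c("a", "p")) else NULL,
                  time = times[i]))
}

# smooth random displacement field: sum of <= 5 Gaussian bumps
random_warp <- function(points, amplitude, smoothness, diam) {
  k <- 5L
  centers <- apply(points, 2, function(col)
    runif(k, min(col), max(col)))
  dirs <- matrix(rnorm(3 * k), k, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  scale <- smoothness * diam
  disp <- matrix(0, nrow(points), 3)
  for (j in seq_len(k)) {
    d2 <- rowSums(sweep(points, 2, centers[j, ])^2)
    w <- exp(-d2 / (2 * scale^2))
    disp <- disp + outer(w, dirs[j, ])
  }
  # normalize so the max displacement magnitude equals amplitude * diam
  mx <- max(sqrt(rowSums(disp^2)))
  if (mx > 0) disp <- disp * (amplitude * diam / mx)
  disp
}

#' Draw one labeled ensemble member
#'
#' Applies per-point Gaussian jitter and a smooth random warp to the
#' reference, then realizes a random subset of the designated inconsistent
#' events through the sample's developmental clock: the sample draws a
#' clock offset (sd \code{spec$clock_sd} minutes) and realizes exactly the
#' events whose time lies behind it, emulating heterochrony.  A realized
#' division replaces the parent by two daughters offset half the local
#' nearest-neighbor distance from it along a random axis; a realized death
#' removes the cell.
#'
#' @param reference cloud from [make_reference()].
#' @param spec the [synthetic_spec()].
#' @param member_seed seed for this member's randomness.
#' @param events designated events (defaults to the spec's designation).
#' @return List with \code{cloud} (named [landmark_cloud]) and
#'   \code{events_realized}.
#' @export
sample_member <- function(reference, spec, member_seed,
                          events = designate_events(reference, spec)) {
  set.seed(member_seed)
  pts <- reference$points
  nm <- reference$names
  diam <- cloud_diameter(pts)
  if (spec$warp_amplitude > 0)
    pts <- pts + random_warp(pts, spec$warp_amplitude,
                             spec$warp_smoothness, diam)
  if (spec$jitter_sigma > 0)
    pts <- pts + matrix(rnorm(length(pts), 0, spec$jitter_sigma * diam),
                        ncol = 3)
  cloud <- landmark_cloud(pts, names = nm, time = reference$time,
                          stage_label = reference$stage_label,
                          source_id = sprintf("member_seed%d", member_seed))
  realized <- list()
  clock <- rnorm(1, 0, spec$clock_sd)   # this sample's developmental age
  for (ev in events) {
    if (ev$time > clock) next                     # not happened here yet
    if (!(ev$subject %in% cloud$names)) next
    realized[[length(realized) + 1L]] <- ev
    if (ev$kind == "death") {
      keep <- cloud$names != ev$subject
      cloud <- landmark_cloud(cloud$points[keep, , drop = FALSE],
                              names = cloud$names[keep], time = cloud$time,
                              stage_label = cloud$stage_label,
                              source_id = cloud$source_id)
    } else {
      ip <- match(ev$subject, cloud$names)
      others <- cloud$points[-ip, , drop = FALSE]
      nnd <- sqrt(min(rowSums(sweep(others, 2, cloud$points[ip, ])^2)))
      axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
      off <- 0.5 * nnd * axis          # daughters at +-0.5*nnd from parent
      keep <- cloud$names != ev$subject
      cloud <- landmark_cloud(
        rbind(cloud$points[keep, , drop = FALSE],
              cloud$points[ip, ] + off, cloud$points[ip, ] - off),
        names = c(cloud$names[keep], ev$daughters), time = cloud$time,
        stage_label = cloud$stage_label, source_id = cloud$source_id)
    }
  }
  list(cloud = cloud, events_realized = realized)
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate the anonymous test cloud with ground truth
#'
#' Draws one more sample like [sample_member()], then applies the modality
#' distortion (anisotropic axis scaling plus a global rotation), strips the
#' names and permutes point order.  Returns the cloud, the ground truth
#' (true name per index and the events realized in this sample), and a
#' correspondence table of 6 well-spread stable landmarks standing in for
#' the manually identified ones.
#'
#' @inheritParams sample_member
#' @param seed seed for this sample.
#' @return List with \code{cloud}, \code{truth} (list: \code{true_names},
#'   \code{events_realized}), and \code{corr} (a [correspondence_table()]).
#' @export
make_unlabeled <- function(reference, spec, seed,
                           events = designate_events(reference, spec)) {
  samp <- sample_member(reference, spec, seed, events)
  set.seed(seed + 5000L)
  pts <- samp$cloud$points
  pts <- sweep(pts, 2, spec$anisotropy, "*") %*% t(random_rotation())
  n <- nrow(pts)
  perm <- sample(n)
  cloud <- landmark_cloud(pts[perm, , drop = FALSE], names = NULL,
                          time = samp$cloud$time, stage_label = "synthetic",
                          source_id = sprintf("unlabeled_seed%d", seed))
  true_names <- samp$cloud$names[perm]
  # 6 far-spread landmarks among cells untouched by any designated event
  touched <- unlist(lapply(events, function(e) c(e$subject, e$daughters)))
  stable <- which(!(true_names %in% touched))
  sel <- stable[farthest_point_sample(cloud$points[stable, , drop = FALSE], 6L)]
  corr <- correspondence_table(true_names[sel], sel)
  list(cloud = cloud,
       truth = list(true_names = setNames(true_names, seq_len(n)),
                    events_realized = samp$events_realized),
       corr = corr)
}

farthest_point_sample <- function(points, k) {
  n <- nrow(points)
  if (n <= k) return(seq_len(n))
  ctr <- colMeans(points)
  sel <- which.max(rowSums(sweep(points, 2, ctr)^2))
  mind <- rowSums(sweep(points, 2, points[sel, ])^2)
  while (length(sel) < k) {
    nxt <- which.max(mind)
    sel <- c(sel, nxt)
    mind <- pmin(mind, rowSums(sweep(points, 2, points[nxt, ])^2))
  }
  sel
}

#' One-call synthetic benchmark instance
#'
#' Builds the full study setup for one seed: reference, designated events,
#' \code{n_members} labeled samples assembled into an ensemble model, and
#' an anonymized test cloud with ground truth and correspondences.
#'
#' @param spec a [synthetic_spec()].
#' @return List: \code{model} (\code{ensemble_model}), \code{unlabeled},
#'   \code{truth}, \code{corr}, \code{reference}, \code{events}.
#' @export
make_benchmark <- function(spec = synthetic_spec()) {
  reference <- make_reference(spec)
  events <- designate_events(reference, spec)
  members <- lapply(seq_len(spec$n_members), function(i)
    sample_member(reference, spec, spec$rng_seed + 100L * i, events))
  model <- build_ensemble_model(lapply(members, `[[`, "cloud"),
                                events, stage_time = 0,
                                window_minutes = 13,
                                stage_label = "synthetic")
  unl <- make_unlabeled(reference, spec, spec$rng_seed + 9000L, events)
  list(model = model, unlabeled = unl$cloud, truth = unl$truth,
       corr = unl$corr, reference = reference, events = events)
}
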