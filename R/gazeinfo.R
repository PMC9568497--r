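.check_annotations <- function(annotations) {
  needed <- c("video_id", "frame_index", "annotator_id",
              "ax_px", "ay_px", "tx_px", "ty_px")
  missing <- setdiff(needed, names(annotations))
  if (length(missing)) {
    stop("annotations: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  annotations
}

# per-frame mean annotated point and its truth
.frame_means <- function(annotations) {
  key <- interaction(annotations$video_id, annotations$frame_index, drop = TRUE)
  out <- do.call(rbind, lapply(split(annotations, key), function(d) {
    data.frame(video_id = d$video_id[1], frame_index = d$frame_index[1],
               mx_px = mean(d$ax_px), my_px = mean(d$ay_px),
               tx_px = d$tx_px[1], ty_px = d$ty_px[1])
  }))
  rownames(out) <- NULL
  out
}

.mean_error_px <- function(frames, tx = frames$tx_px, ty = frames$ty_px) {
  mean(sqrt((frames$mx_px - tx)^2 + (frames$my_px - ty)^2))
}

#' Gaze-location estimation error
#'
#' Per frame, the annotated points are averaged across annotators and the
#' Euclidean distance to the ground-truth gazed location is taken; the
#' result is the mean over frames, reported in pixels and (via the display
#' geometry) in degrees. Averaging annotators before taking the distance
#' reflects a "mean annotated gazed location" reading; per-annotator
#' distances are available via `average_first = FALSE`.
#'
#' @param annotations Annotation data.frame (see [simulate_annotations()]).
#' @param geometry A [screen_geometry()] for the degree conversion.
#' @param average_first Average annotators before the distance (default)
#'   or average per-annotator distances.
#' @return A list with `mean_error_px`, `mean_error_deg`, `n_frames`.
#' @export
estimation_error <- function(annotations, geometry = screen_geometry(),
                             average_first = TRUE) {
  a <- .check_annotations(annotations)
  if (average_first) {
    frames <- .frame_means(a)
    err_px <- sqrt((frames$mx_px - frames$tx_px)^2 +
                     (frames$my_px - frames$ty_px)^2)
  } else {
    key <- interaction(a$video_id, a$frame_index, drop = TRUE)
    err_px <- vapply(split(a, key), function(d) {
      mean(sqrt((d$ax_px - d$tx_px)^2 + (d$ay_px - d$ty_px)^2))
    }, numeric(1))
    frames <- NULL
  }
  ppd <- pixels_per_degree(geometry)
  # component-wise conversion; exact for isotropic rasters
  err_deg <- if (average_first) {
    sqrt(((frames$mx_px - frames$tx_px) / ppd["x"])^2 +
           ((frames$my_px - frames$ty_px) / ppd["y"])^2)
  } else {
    err_px / mean(ppd)
  }
  list(mean_error_px = mean(err_px), mean_error_deg = mean(err_deg),
       n_frames = length(err_px))
}

#' Permutation baseline for the estimation error
#'
#' The chance-level control: the pairing between videos' annotation tracks
#' and videos' ground-truth locations is permuted across videos (frames
#' keep their within-video order; a donor video's truth is indexed
#' cyclically when frame counts differ), and the mean estimation error is
#' recomputed per permutation. Exhaustive over all permutations when
#' feasible, Monte-Carlo otherwise.
#'
#' @param annotations Annotation data.frame.
#' @param geometry A [screen_geometry()].
#' @param n_perm Number of Monte-Carlo permutations.
#' @param exhaustive Force exhaustive enumeration (all factorial(n_videos)
#'   permutations); automatic for <= 5 videos.
#' @param seed Optional integer seed.
#' @return A list with `baseline_mean_px`, `baseline_mean_deg`, `ci_px`
#'   (2.5/97.5 percentiles), `n_permutations`, and `errors_px` (the
#'   permutation distribution).
#' @export
permutation_baseline <- function(annotations, geometry = screen_geometry(),
                                 n_perm = 1000, exhaustive = NULL,
                                 seed = NULL) {
  a <- .check_annotations(annotations)
  frames <- .frame_means(a)
  videos <- unique(frames$video_id)
  nv <- length(videos)
  if (nv < 2) {
    stop("permutation_baseline: need >= 2 distinct videos/trials", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(exhaustive)) exhaustive <- nv <= 5

  truth_of <- lapply(videos, function(v) {
    frames[frames$video_id == v, c("tx_px", "ty_px"), drop = FALSE]
  })
  ann_of <- lapply(videos, function(v) {
    frames[frames$video_id == v, c("mx_px", "my_px"), drop = FALSE]
  })

  error_for_perm <- function(perm) {
    errs <- unlist(lapply(seq_len(nv), function(i) {
      ann <- ann_of[[i]]
      tr <- truth_of[[perm[i]]]
      # cyclic frame indexing when the donor video has fewer frames
      j <- ((seq_len(nrow(ann)) - 1L) %% nrow(tr)) + 1L
      sqrt((ann$mx_px - tr$tx_px[j])^2 + (ann$my_px - tr$ty_px[j])^2)
    }))
    mean(errs)
  }

  perms <- if (exhaustive) {
    .all_permutations(nv)
  } else {
    lapply(seq_len(n_perm), function(i) sample.int(nv))
  }
  errors <- vapply(perms, error_for_perm, numeric(1))
  ppd <- mean(pixels_per_degree(geometry))
  list(baseline_mean_px = mean(errors),
       baseline_mean_deg = mean(errors) / ppd,
       ci_px = stats::quantile(errors, c(0.025, 0.975), names = FALSE),
       n_permutations = length(errors),
       errors_px = errors)
}

.all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .all_permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Full gaze-information summary
#'
#' Observed estimation error plus its permutation baseline, per condition.
#'
#' @param annotations Annotation data.frame (may mix conditions).
#' @param geometry A [screen_geometry()].
#' @param n_perm Permutations for the baseline.
#' @param seed Optional integer seed.
#' @return Data.frame with one row per condition: observed and baseline
#'   errors in px and deg, frame and permutation counts.
#' @export
gaze_information <- function(annotations, geometry = screen_geometry(),
                             n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conds <- unique(annotations$condition)
  out <- do.call(rbind, lapply(conds, function(cd) {
    a <- annotations[annotations$condition == cd, , drop = FALSE]
    obs <- estimation_error(a, geometry)
    base <- permutation_baseline(a, geometry, n_perm = n_perm)
    data.frame(condition = cd,
               mean_error_px = obs$mean_error_px,
               mean_error_deg = obs$mean_error_deg,
               n_frames = obs$n_frames,
               baseline_mean_px = base$baseline_mean_px,
               baseline_mean_deg = base$baseline_mean_deg,
               n_permutations = base$n_permutations)
  }))
  rownames(out) <- NULL
  out
}
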