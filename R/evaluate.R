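# Accuracy and robustness metrics: FP/FN accounting against phantom ground
# truth, paired distances between reconstructions, and the target-displacement
# robustness experiment.

#' Displace a planned target perpendicular to its trajectory
#'
#' Draws a point uniformly on the circle of the given radius centred at the
#' target and lying in the plane perpendicular to the entry-target axis.
#' This emulates the surgical reality that planned target points can deviate
#' by up to tens of millimetres while entry points (fixed by the skull
#' screw) barely move. Uses the current RNG stream; seed upstream.
#'
#' @param entry,target Planned entry and target (mm); must differ.
#' @param radius Displacement radius in mm (`0` returns the target itself).
#' @return The displaced target (mm), at exactly `radius` from `target` and
#'   perpendicular to the axis.
#' @export
displace_target <- function(entry, target, radius) {
  entry <- .as_point3(entry, "entry"); target <- .as_point3(target, "target")
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    stop("'radius' must be a non-negative scalar", call. = FALSE)
  u <- .unit(target - entry)
  if (radius == 0) return(target)
  ref <- if (abs(u[3]) > 0.9) c(0, 1, 0) else c(0, 0, 1)
  e1 <- .unit(.cross3(u, ref))
  e2 <- .cross3(u, e1)
  phi <- stats::runif(1, 0, 2 * pi)
  target + radius * (cos(phi) * e1 + sin(phi) * e2)
}

# displace every trajectory's target by `radius` (one RNG draw each)
.displace_trajectories <- function(trajectories, radius) {
  lapply(trajectories, function(tr)
    planned_trajectory(tr$label, tr$entry,
                       displace_target(tr$entry, tr$target, radius),
                       tr$in_ct_space))
}

#' Compare a segmentation against phantom ground truth
#'
#' Per electrode, predictions and truth contacts are matched greedily by
#' nearest distance within `match_tol`; matched pairs contribute to the
#' localization error, unmatched truth contacts are false negatives and
#' unmatched predictions false positives, both normalized by the total
#' number of true contacts. The default tolerance of half the contact pitch
#' (1.75 mm) is the distance beyond which a detection becomes ambiguous
#' between neighbouring contacts.
#'
#' @param predicted A `seeg_implant`.
#' @param truth A `phantom_truth`.
#' @param match_tol Matching tolerance in mm.
#' @return An object of class `seeg_eval`: `mean_error`, `sd_error`, counts,
#'   `fp_rate`, `fn_rate` and a per-electrode data frame.
#' @export
evaluate <- function(predicted, truth, match_tol = 1.75) {
  stopifnot(inherits(predicted, "seeg_implant"),
            inherits(truth, "phantom_truth"))
  errors <- numeric()
  fp <- 0L; fn <- 0L; total <- 0L
  per <- list()
  for (el in truth$electrodes) {
    tc <- el$contacts[stats::complete.cases(el$contacts), , drop = FALSE]
    total <- total + el$n_contacts
    pred <- predicted$electrodes[[el$label]]
    pc <- if (is.null(pred)) matrix(numeric(), 0, 3) else pred$contacts
    nt <- nrow(tc); np <- nrow(pc)
    matched <- 0L
    errs <- numeric()
    if (nt > 0L && np > 0L) {
      D <- sqrt(pmax(outer(rowSums(pc^2), rowSums(tc^2), `+`) -
                     2 * pc %*% t(tc), 0))
      repeat {
        m <- which(D == min(D), arr.ind = TRUE)[1, , drop = TRUE]
        if (!is.finite(D[m[1], m[2]]) || D[m[1], m[2]] > match_tol) break
        errs <- c(errs, D[m[1], m[2]])
        matched <- matched + 1L
        D[m[1], ] <- Inf
        D[, m[2]] <- Inf
        if (all(!is.finite(D))) break
      }
    }
    el_fn <- el$n_contacts - matched
    el_fp <- np - matched
    fn <- fn + el_fn; fp <- fp + el_fp
    errors <- c(errors, errs)
    per[[el$label]] <- data.frame(label = el$label, n_true = el$n_contacts,
                                  n_pred = np, matched = matched,
                                  fn = el_fn, fp = el_fp,
                                  mean_error = if (matched) mean(errs) else NA_real_)
  }
  structure(list(mean_error = if (length(errors)) mean(errors) else NA_real_,
                 sd_error = if (length(errors) > 1) stats::sd(errors) else NA_real_,
                 n_matched = length(errors), fp = fp, fn = fn,
                 total_true = total,
                 fp_rate = fp / total, fn_rate = fn / total,
                 per_electrode = do.call(rbind, per)),
            class = "seeg_eval")
}

#' @export
print.seeg_eval <- function(x, ...) {
  cat(sprintf(
    "<seeg_eval> %d/%d contacts matched, error %.4f +/- %.4f mm, FP %.1f%%, FN %.1f%%\n",
    x$n_matched, x$total_true, x$mean_error, x$sd_error,
    100 * x$fp_rate, 100 * x$fn_rate))
  invisible(x)
}

# mean per-contact distance between two reconstructions of the same implant,
# pairing contacts by electrode label and contact index
.paired_distances <- function(a, b) {
  out <- numeric()
  for (lab in intersect(names(a$electrodes), names(b$electrodes))) {
    ca <- a$electrodes[[lab]]$contacts
    cb <- b$electrodes[[lab]]$contacts
    n <- min(nrow(ca), nrow(cb))
    if (n == 0L) next
    out <- c(out, sqrt(rowSums((ca[seq_len(n), , drop = FALSE] -
                                cb[seq_len(n), , drop = FALSE])^2)))
  }
  out
}

#' Target-displacement robustness experiment
#'
#' Reproduces the displacement experiment: for each radius, every planned
#' target of the phantom is displaced on the perpendicular circle (all
#' electrodes at once, the worst case), the implant re-segmented, and the
#' result compared (i) against the undisplaced reconstruction — paired
#' per-contact distance, the robustness error — and (ii) against ground
#' truth — FP/FN rates. The two comparisons answer different questions and
#' are reported separately.
#'
#' @param phantom A `seeg_phantom` from [make_phantom()], or a
#'   [phantom_spec()] (then generated here).
#' @param radii Displacement radii in mm; default the 8-radius grid spanning
#'   1-15 mm.
#' @param n_samples Displacement samples per radius (default 5).
#' @param seed Seed for the displacement draws.
#' @param config A [seg_config()]; its threshold defaults to the phantom's.
#' @param match_tol Truth-matching tolerance in mm.
#' @return An object of class `seeg_robustness`: `samples` (one row per
#'   radius x sample: mean paired error, n pairs, FP/FN rates), `summary`
#'   (per radius: mean error with 5th/95th percentiles, mean rates), plus
#'   the `reference` reconstruction and the `truth`.
#' @export
robustness_experiment <- function(phantom, radii = seq(1, 15, by = 2),
                                  n_samples = 5L, seed = 1L,
                                  config = NULL, match_tol = 1.75) {
  if (inherits(phantom, "phantom_spec")) phantom <- make_phantom(phantom)
  stopifnot(inherits(phantom, "seeg_phantom"))
  if (is.null(config)) config <- seg_config(threshold = phantom$spec$threshold)
  vol <- apply_threshold(phantom$volume, config$threshold)
  trajs <- phantom_trajectories(phantom)
  models <- phantom_models(phantom)
  reference <- segment_implant(vol, trajs, models, config)
  rows <- .with_seed(seed, function() {
    out <- list()
    for (r in radii) {
      for (s in seq_len(n_samples)) {
        dtr <- .displace_trajectories(trajs, r)
        run <- segment_implant(vol, dtr, models, config)
        pd <- .paired_distances(run, reference)
        ev <- evaluate(run, phantom$truth, match_tol)
        out[[length(out) + 1L]] <- data.frame(
          radius = r, sample = s,
          mean_paired = if (length(pd)) mean(pd) else NA_real_,
          n_pairs = length(pd),
          fn_rate = ev$fn_rate, fp_rate = ev$fp_rate)
      }
    }
    do.call(rbind, out)
  })
  summ <- do.call(rbind, lapply(split(rows, rows$radius), function(g)
    data.frame(radius = g$radius[1],
               mean_paired = mean(g$mean_paired, na.rm = TRUE),
               p5 = stats::quantile(g$mean_paired, 0.05, na.rm = TRUE,
                                    names = FALSE),
               p95 = stats::quantile(g$mean_paired, 0.95, na.rm = TRUE,
                                     names = FALSE),
               fn_rate = mean(g$fn_rate), fp_rate = mean(g$fp_rate))))
  rownames(summ) <- NULL
  structure(list(samples = rows, summary = summ, reference = reference,
                 truth = phantom$truth),
            class = "seeg_robustness")
}

#' @export
print.seeg_robustness <- function(x, ...) {
  cat("<seeg_robustness> paired error vs undisplaced run by radius (mm):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
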