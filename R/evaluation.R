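# Evaluation: Dice overlap, Bland-Altman agreement, parameter optimization
# harness, initialization-stability sweep.

#' Dice overlap coefficient between two contours
#'
#' `2|A n B| / (|A| + |B|)` over interior pixel sets, rasterized on `grid`
#' with the same pixel-center rule used by the flow sums.
#'
#' @param a,b [pc_contour()] objects.
#' @param grid image dim `c(H, W)`.
#' @return Overlap fraction in `[0, 1]`.
#' @export
dice <- function(a, b, grid) {
  ma <- contour_mask(a, grid)
  mb <- contour_mask(b, grid)
  denom <- sum(ma) + sum(mb)
  if (denom == 0L) stop("both contours rasterize to empty pixel sets")
  2 * sum(ma & mb) / denom
}

#' Bland-Altman agreement statistics
#'
#' Bias and variability between paired measurements are the mean and one
#' sample standard deviation of the differences `x - y`; the 95% limits of
#' agreement are `bias +/- 1.96 SD`.
#'
#' @param pairs n x 2 matrix or data frame of paired measurements `(x, y)`,
#'   n >= 2.
#' @return A `pc_agreement`: list with `bias`, `variability`, `loa_low`,
#'   `loa_high`, `n`.
#' @export
bland_altman <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2L || ncol(pairs) != 2L) {
    stop("need at least 2 pairs of measurements")
  }
  d <- pairs[, 1L] - pairs[, 2L]
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(bias = bias, variability = s,
         loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         n = nrow(pairs)),
    class = "pc_agreement"
  )
}

#' @export
print.pc_agreement <- function(x, ...) {
  cat(sprintf("<pc_agreement> bias %.3f +/- %.3f (n=%d), 95%% LoA [%.3f, %.3f]\n",
              x$bias, x$variability, x$n, x$loa_low, x$loa_high))
  invisible(x)
}

# per-frame Dice of a segmentation against ground truth
dice_per_phase <- function(seg, truth, grid) {
  vapply(seq_along(seg$contours), function(i) {
    dice(seg$contours[[i]], truth$contours[[i]], grid)
  }, numeric(1L))
}

# merge a named list / one-row data frame of overrides into algorithm_params
merge_params <- function(base, overrides) {
  p <- unclass(base)
  for (nm in names(overrides)) {
    if (!nm %in% names(p)) stop("unknown algorithm parameter: ", nm)
    p[[nm]] <- overrides[[nm]]
  }
  do.call(algorithm_params, p)
}

#' Grid optimization of algorithm parameters
#'
#' Scores each candidate combination of snake/shape parameters on a training
#' set of series with reference segmentations. Following the nested design,
#' the best diameter `scale_factor` is determined per combination by a 1-D
#' sweep (segmentation is run once per combination at unit scale; rescaling
#' commutes with the earlier steps), and the combination score is
#' `mean(Dice) - lambda_var * SD(Dice)` over all training frames: a large
#' mean overlap without overexpressed variability. Failing combinations score
#' `-Inf` and are kept in the table.
#'
#' @param grid data frame of parameter overrides, one combination per row
#'   (columns named as in [algorithm_params()], excluding `scale_factor`).
#' @param training list of training cases, each a list with `series`
#'   ([pc_series()]) and `truth` ([pc_segmentation()]).
#' @param model a `pc_shape_model` for the PCA mode.
#' @param lambda_var weight of the Dice-variability penalty.
#' @param scale_factors candidate diameter rescale factors.
#' @param base_params defaults for parameters not in `grid`.
#' @param seed_rr_fraction RR fraction of the phase whose ground-truth contour
#'   seeds each training segmentation.
#' @return List with `params` (the winning [algorithm_params()]) and `table`
#'   (per-combination best scale, mean/SD Dice and score).
#' @export
optimize_parameters <- function(grid, training, model, lambda_var = 1,
                                scale_factors = seq(0.95, 1.15, by = 0.025),
                                base_params = algorithm_params(),
                                seed_rr_fraction = 0.2) {
  stopifnot(nrow(grid) >= 1L, length(training) >= 1L)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    overrides <- as.list(grid[i, , drop = FALSE])
    comb <- tryCatch(
      merge_params(base_params, c(overrides, list(scale_factor = 1.0))),
      error = function(e) NULL
    )
    if (is.null(comb)) {
      return(data.frame(row = i, scale_factor = NA_real_, mean_dice = NA_real_,
                        sd_dice = NA_real_, score = -Inf))
    }
    # one segmentation per training case at unit scale; sweep the rescale
    segs <- tryCatch(
      lapply(training, function(case) {
        T_ <- n_phases(case$series)
        sp <- pmin(max(round(seed_rr_fraction * T_), 0L), T_ - 1L)
        seed <- case$truth$contours[[sp + 1L]]
        segment_series(case$series, seed, model, comb)
      }),
      error = function(e) NULL
    )
    if (is.null(segs)) {
      return(data.frame(row = i, scale_factor = NA_real_, mean_dice = NA_real_,
                        sd_dice = NA_real_, score = -Inf))
    }
    per_scale <- lapply(scale_factors, function(sf) {
      unlist(lapply(seq_along(training), function(j) {
        grid_dim <- dim(training[[j]]$series$magnitude)[2:3]
        scaled <- segs[[j]]
        scaled$contours <- lapply(scaled$contours, rescale_contour, scale_factor = sf)
        dice_per_phase(scaled, training[[j]]$truth, grid_dim)
      }))
    })
    scores <- vapply(per_scale, function(dv) {
      mean(dv) - lambda_var * stats::sd(dv)
    }, numeric(1L))
    k <- which.max(scores)
    data.frame(row = i, scale_factor = scale_factors[k],
               mean_dice = mean(per_scale[[k]]),
               sd_dice = stats::sd(per_scale[[k]]), score = scores[k])
  })
  table <- cbind(do.call(rbind, rows), grid)
  best <- which.max(table$score)
  if (!is.finite(table$score[best])) stop("every parameter combination failed")
  winning <- merge_params(
    base_params,
    c(as.list(grid[best, , drop = FALSE]),
      list(scale_factor = table$scale_factor[best]))
  )
  list(params = winning, table = table)
}

#' Initialization-stability sweep
#'
#' Re-runs the full segmentation seeded at `n_points_on_rr` equidistant
#' fractions of the RR interval (using the ground-truth contour at each seed
#' phase as the manual delineation) and reports the resulting net flow volume
#' and mean Dice per seed.
#'
#' @param series a [pc_series()].
#' @param truth ground-truth [pc_segmentation()].
#' @param model a `pc_shape_model`.
#' @param params an [algorithm_params()].
#' @param n_points_on_rr number of equidistant seed time points (>= 2).
#' @param correct_background passed to [quantify_flow()].
#' @return Data frame with `seed_fraction`, `seed_phase`, `net_volume`,
#'   `mean_dice`.
#' @export
initialization_sweep <- function(series, truth, model,
                                 params = algorithm_params(),
                                 n_points_on_rr = 20L,
                                 correct_background = TRUE) {
  stopifnot(n_points_on_rr >= 2L)
  T_ <- n_phases(series)
  grid_dim <- dim(series$magnitude)[2:3]
  fractions <- (seq_len(n_points_on_rr) - 1L) / n_points_on_rr
  rows <- lapply(fractions, function(f) {
    sp <- min(floor(f * T_), T_ - 1L)
    seed <- truth$contours[[sp + 1L]]
    seg <- segment_series(series, seed, model, params)
    fl <- quantify_flow(series, seg, correct_background = correct_background)
    data.frame(seed_fraction = f, seed_phase = sp,
               net_volume = fl$net_volume,
               mean_dice = mean(dice_per_phase(seg, truth, grid_dim)))
  })
  do.call(rbind, rows)
}
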