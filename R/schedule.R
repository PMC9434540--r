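# Learning-rate schedule (1cycle) and learning-rate range test.

#' 1cycle learning-rate schedule
#'
#' A single unimodal cycle evaluated per batch step: a cosine rise from
#' `lr_min` to `lr_max` peaking at `pct_peak` of the cycle, followed by a
#' cosine fall back to `lr_min`. `one_cycle_lr(0, ...)` is exactly
#' `lr_min` and the trace attains exactly `lr_max` at the peak step.
#'
#' @param step 0-based step index, `0 <= step < total_steps`. Vectorized.
#' @param total_steps Total number of steps in the cycle.
#' @param lr_min,lr_max Lower and upper bounds (`lr_min < lr_max`).
#' @param pct_peak Fraction of the cycle spent rising (default 0.3).
#' @return Learning rate(s).
#' @export
one_cycle_lr <- function(step, total_steps, lr_min = 0.0063,
                         lr_max = 0.1584, pct_peak = 0.3) {
  assert_that(lr_min < lr_max, "lr_min must be below lr_max")
  assert_that(all(step >= 0 & step < total_steps),
              "step must satisfy 0 <= step < total_steps")
  if (total_steps == 1) return(rep(lr_max, length(step)))
  peak <- max(1, min(total_steps - 2, round(pct_peak * (total_steps - 1))))
  rise <- step <= peak
  lr <- numeric(length(step))
  lr[rise] <- lr_min + (lr_max - lr_min) *
    (1 - cos(pi * step[rise] / peak)) / 2
  lr[!rise] <- lr_min + (lr_max - lr_min) *
    (1 + cos(pi * (step[!rise] - peak) / (total_steps - 1 - peak))) / 2
  lr
}

#' Learning-rate range test
#'
#' Sweeps the learning rate exponentially from `lr_lo` to `lr_hi` over
#' `n_steps` optimization steps, records an exponentially smoothed loss,
#' and suggests the learning rate at the steepest descent of the smoothed
#' loss — the usual recipe for picking the 1cycle peak rate.
#'
#' @param step_fn Stateful closure: called as `step_fn(lr)`, performs one
#'   optimization step at that learning rate and returns the (scalar) batch
#'   loss.
#' @param lr_lo,lr_hi Sweep bounds.
#' @param n_steps Number of steps (>= 10).
#' @param beta Smoothing coefficient for the loss trace.
#' @return List with `suggested_lr`, and the full `trace` data frame
#'   (`step`, `lr`, `loss`, `smoothed`).
#' @export
lr_range_test <- function(step_fn, lr_lo = 1e-5, lr_hi = 1, n_steps = 50,
                          beta = 0.9) {
  assert_that(n_steps >= 10, "n_steps must be >= 10")
  lrs <- exp(seq(log(lr_lo), log(lr_hi), length.out = n_steps))
  loss <- numeric(n_steps)
  sm <- numeric(n_steps)
  avg <- 0
  for (s in seq_len(n_steps)) {
    loss[s] <- step_fn(lrs[s])
    avg <- beta * avg + (1 - beta) * loss[s]
    sm[s] <- avg / (1 - beta^s)   # bias-corrected
  }
  ok <- is.finite(sm)
  if (!any(ok)) {
    stop("diagnostic error: loss diverged at every learning rate",
         call. = FALSE)
  }
  slope <- diff(sm) / diff(log(lrs))
  slope[!is.finite(slope)] <- Inf
  i <- which.min(slope)
  list(suggested_lr = lrs[i],
       trace = data.frame(step = seq_len(n_steps), lr = lrs, loss = loss,
                          smoothed = sm))
}
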