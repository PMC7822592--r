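## Plasma-stability kinetics: first-order decay fits on concentration time
## courses, ex vivo (decay from t = 0) and in vivo (declining phase after
## the post-injection peak, normalized to the peak value).

#' Construct a decay curve
#'
#' @param records data.frame with columns `time_min`, `conc_ng_ml`,
#'   `replicate_id` (see [read_timecourse()]).
#' @param baseline_time time defining T0 for normalization (default 0 min).
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(records, baseline_time = 0) {
  need <- c("time_min", "conc_ng_ml", "replicate_id")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(records$time_min < 0)) stop("times must be non-negative")
  if (any(records$conc_ng_ml < 0)) stop("concentrations must be non-negative")
  npts <- tapply(records$time_min, records$replicate_id,
                 function(t) length(unique(t)))
  if (any(npts < 2)) {
    stop("each replicate needs at least 2 distinct time points")
  }
  structure(list(records = records, baseline_time = baseline_time),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  r <- x$records
  cat(sprintf("decay_curve: %d records, %d replicate(s), t = %g..%g min (T0 = %g)\n",
              nrow(r), length(unique(r$replicate_id)), min(r$time_min),
              max(r$time_min), x$baseline_time))
  invisible(x)
}

#' Normalize a decay curve to its baseline (T0 = 100%)
#'
#' Each replicate is scaled independently so that its concentration at the
#' baseline time becomes 100%, mirroring how time courses are expressed as
#' percent of the initial concentration.
#'
#' @param curve a `decay_curve`.
#' @return A `decay_curve` in percent of baseline.
#' @export
normalize_to_baseline <- function(curve) {
  r <- curve$records
  out <- lapply(split(r, r$replicate_id), function(d) {
    at0 <- d$conc_ng_ml[d$time_min == curve$baseline_time]
    if (length(at0) == 0L) {
      stop("replicate ", d$replicate_id[1], " has no record at baseline time ",
           curve$baseline_time)
    }
    b <- mean(at0)
    if (b == 0) stop("zero baseline in replicate ", d$replicate_id[1])
    d$conc_ng_ml <- d$conc_ng_ml / b * 100
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  decay_curve(out, baseline_time = curve$baseline_time)
}

#' Fit a first-order decay model
#'
#' Default method is ordinary least squares of `log(concentration)` on time,
#' pooled across replicates; `method = "nls"` instead fits
#' `C(t) = C0 * exp(-k t)` by Levenberg-Marquardt nonlinear least squares.
#' Confidence intervals for the half-life come from a seeded nonparametric
#' bootstrap over replicates. A preparation is called stable when the 95%
#' confidence interval of the decay rate includes zero or the fitted
#' half-life exceeds four times the observation window.
#'
#' @param curve a `decay_curve` (typically already in percent of baseline).
#' @param method `"loglinear"` (default) or `"nls"`.
#' @param n_boot bootstrap resamples for the CI (default 1000; 0 skips the
#'   bootstrap and returns NA intervals).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return An object of class `half_life_estimate` with fields `t_half`
#'   (min), `rate_k` (1/min), `ci_low`, `ci_high`, `method`, `n_replicates`,
#'   `mode`, `stable`.
#' @examples
#' tc <- simulate_decay(decay_truth(t_half = 120, noise_cv = 0, seed = 1))
#' fit_first_order(normalize_to_baseline(tc), n_boot = 0)
#' @export
fit_first_order <- function(curve, method = c("loglinear", "nls"),
                            n_boot = 1000, conf = 0.95, seed = 1L) {
  method <- match.arg(method)
  r <- curve$records
  pos <- r[r$conc_ng_ml > 0, ]
  if (nrow(pos) < 3L) stop("need at least 3 positive concentrations")
  if (length(unique(pos$time_min)) < 2L) stop("need at least 2 time points")
  fit <- .fit_k(pos, method)
  k <- fit$k
  t_half <- if (k <= 0) Inf else log(2) / k
  reps <- unique(r$replicate_id)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && length(reps) > 1L) {
    set.seed(seed)
    boot_t <- vapply(seq_len(n_boot), function(b) {
      pick <- sample(reps, length(reps), replace = TRUE)
      d <- do.call(rbind, lapply(pick, function(id) pos[pos$replicate_id == id, ]))
      kb <- .fit_k(d, method)$k
      if (kb <= 0) Inf else log(2) / kb
    }, numeric(1))
    ci <- unname(stats::quantile(boot_t, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                                 na.rm = TRUE, names = FALSE))
  }
  window <- diff(range(r$time_min))
  stable <- (!is.na(fit$k_ci_low) && fit$k_ci_low <= 0) ||
    !is.finite(t_half) || t_half > 4 * window
  structure(
    list(t_half = t_half, rate_k = k, ci_low = ci[1], ci_high = ci[2],
         method = method, n_replicates = length(reps),
         mode = "ex_vivo", stable = stable),
    class = "half_life_estimate"
  )
}

## Point fit of the decay rate k (1/min); also an analytic CI for k from the
## log-linear slope, used for the stability call.
.fit_k <- function(d, method) {
  if (method == "loglinear") {
    fit <- stats::lm(log(conc_ng_ml) ~ time_min, data = d)
    k <- -unname(stats::coef(fit)[2])
    ## suppressed: summary.lm warns on zero-residual (noiseless) input
    se <- suppressWarnings(summary(fit))$coefficients[2, 2]
    tcrit <- stats::qt(0.975, df = stats::df.residual(fit))
    list(k = k, k_ci_low = k - tcrit * se, k_ci_high = k + tcrit * se)
  } else {
    start_k <- max(1e-8, .fit_k(d, "loglinear")$k)
    fit <- minpack.lm::nlsLM(
      conc_ng_ml ~ C0 * exp(-k * time_min), data = d,
      start = list(C0 = max(d$conc_ng_ml), k = start_k),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    co <- summary(fit)$coefficients
    k <- unname(co["k", "Estimate"]); se <- co["k", "Std. Error"]
    list(k = k, k_ci_low = k - 1.96 * se, k_ci_high = k + 1.96 * se)
  }
}

#' Fit the declining-phase half-life of an in vivo time course
#'
#' Discards all records before the peak time, renormalizes each replicate so
#' its value at the peak is 100%, and fits first-order decay to what
#' remains. This reproduces the convention of expressing post-injection
#' serum levels as a percentage of the maximum reached at 30 min and fitting
#' only the declining phase.
#'
#' @param curve a `decay_curve` of the full post-injection time course.
#' @param t_peak peak time in minutes (default 30).
#' @inheritParams fit_first_order
#' @return A `half_life_estimate` with `mode = "in_vivo_declining"`.
#' @export
fit_declining_phase <- function(curve, t_peak = 30,
                                method = c("loglinear", "nls"),
                                n_boot = 1000, conf = 0.95, seed = 1L) {
  r <- curve$records[curve$records$time_min >= t_peak, ]
  if (nrow(r) == 0L) stop("no records at or after t_peak = ", t_peak)
  post <- decay_curve(r, baseline_time = t_peak)
  est <- fit_first_order(normalize_to_baseline(post), method = method,
                         n_boot = n_boot, conf = conf, seed = seed)
  est$mode <- "in_vivo_declining"
  est
}

#' @export
print.half_life_estimate <- function(x, ...) {
  th <- if (is.finite(x$t_half)) sprintf("%.2f min", x$t_half) else "Inf (stable)"
  cat(sprintf("half-life %s (k = %.5g /min, %s fit, %d replicate(s), %s)\n",
              th, x$rate_k, x$method, x$n_replicates, x$mode))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  95%% bootstrap CI: [%.2f, %.2f] min\n", x$ci_low, x$ci_high))
  }
  if (x$stable) cat("  flagged STABLE over the observation window\n")
  invisible(x)
}

#' Percent of initial concentration remaining after time t
#'
#' @param t elapsed time in minutes.
#' @param t_half half-life in minutes (> 0).
#' @return `100 * 2^(-t / t_half)`.
#' @examples
#' percent_remaining(180, 180)  # 50
#' @export
percent_remaining <- function(t, t_half) {
  if (any(t_half <= 0)) stop("t_half must be positive")
  100 * 2^(-t / t_half)
}

#' Descriptive percent-remaining summary across conditions
#'
#' For inhibitor / temperature / protease-gradient experiments read out at a
#' single common time: mean percent remaining per condition with SEM across
#' replicates (SEM is NA for a single replicate). No dose-response model is
#' fitted.
#'
#' @param curves named list of `decay_curve` objects, one per condition,
#'   each already normalized to percent of baseline (see
#'   [normalize_to_baseline()]).
#' @param eval_time common evaluation time in minutes.
#' @return data.frame with columns `condition`, `mean_percent_remaining`,
#'   `sem`, `n`.
#' @export
condition_summary <- function(curves, eval_time) {
  if (is.null(names(curves)) || any(names(curves) == "")) {
    stop("curves must be a named list (names = condition labels)")
  }
  rows <- lapply(names(curves), function(cond) {
    r <- curves[[cond]]$records
    at <- r[r$time_min == eval_time, ]
    if (nrow(at) == 0L) {
      stop("condition '", cond, "' has no record at time ", eval_time)
    }
    vals <- tapply(at$conc_ng_ml, at$replicate_id, mean)
    data.frame(
      condition = cond,
      mean_percent_remaining = mean(vals),
      sem = if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals)) else NA_real_,
      n = length(vals),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
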