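#' Fit the terminal elimination rate constant
#'
#' Ordinary least squares of `ln C` on `t` over a terminal subset of the
#' profile. Two selection strategies:
#' \describe{
#'   \item{`best_adj_r2` (default)}{scan all suffixes of length 3 up to
#'     n-1 points that exclude the global maximum concentration, pick the
#'     one with maximal adjusted R-squared; ties go to the longer suffix.}
#'   \item{`fixed_n`}{use exactly the last `n_points` points.}
#' }
#' The fitted slope must be negative (a terminal decline); otherwise an
#' estimation error is raised.
#'
#' @param profile A [conc_profile()] with at least 3 candidate points.
#' @param strategy `"best_adj_r2"` or `"fixed_n"`.
#' @param n_points Number of terminal points for `fixed_n`.
#' @param min_points Minimum points in any candidate fit; default 3.
#' @return A list with `lambda_z` (1/day), `intercept` (ln ug/mL at t=0),
#'   `r2_adj`, and `points_used` (integer count).
#' @export
fit_lambda_z <- function(profile, strategy = c("best_adj_r2", "fixed_n"),
                         n_points = 3L, min_points = 3L) {
  stopifnot(inherits(profile, "conc_profile"))
  strategy <- match.arg(strategy)
  t <- profile$time
  y <- log(profile$conc)
  n <- length(t)

  fit_one <- function(idx) {
    ti <- t[idx]; yi <- y[idx]; k <- length(idx)
    tb <- mean(ti); yb <- mean(yi)
    sxx <- sum((ti - tb)^2)
    slope <- sum((ti - tb) * (yi - yb)) / sxx
    intercept <- yb - slope * tb
    ss_res <- sum((yi - intercept - slope * ti)^2)
    ss_tot <- sum((yi - yb)^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    r2_adj <- if (k > 2) 1 - (1 - r2) * (k - 1) / (k - 2) else r2
    list(slope = slope, intercept = intercept, r2_adj = r2_adj, k = k)
  }

  if (strategy == "fixed_n") {
    if (n_points < min_points)
      stop(sprintf("n_points must be >= %d", min_points), call. = FALSE)
    if (n < n_points)
      stop(sprintf("profile has %d points, need %d", n, n_points),
           call. = FALSE)
    best <- fit_one(seq.int(n - n_points + 1L, n))
  } else {
    i_cmax <- which.max(profile$conc)
    # suffixes of length min_points..(n-1), never reaching back to Cmax
    first_allowed <- max(2L, i_cmax + 1L)
    max_len <- n - first_allowed + 1L
    if (max_len < min_points) {
      # degenerate short profile: fall back to the last min_points points
      # so that e.g. a flat 3-point tail still reports 'no terminal decline'
      if (n < min_points)
        stop(sprintf("fewer than %d points for terminal fit", min_points),
             call. = FALSE)
      best <- fit_one(seq.int(n - min_points + 1L, n))
    } else {
      best <- NULL
      for (k in seq.int(min_points, max_len)) {
        cand <- fit_one(seq.int(n - k + 1L, n))
        if (is.null(best) || cand$r2_adj >= best$r2_adj - 1e-12)
          best <- cand  # >= with tolerance: ties go to more points
      }
    }
  }

  if (best$slope >= 0)
    stop("no terminal decline (nonnegative terminal slope)", call. = FALSE)
  list(lambda_z = -best$slope, intercept = best$intercept,
       r2_adj = best$r2_adj, points_used = best$k)
}

#' Trapezoidal AUC to the last observation
#'
#' `"linear"`: standard trapezoids. `"linear_up_log_down"` (the default
#' elsewhere in the package): segments where concentration falls use the
#' logarithmic trapezoid `(t2-t1)(C1-C2)/ln(C1/C2)` -- exact on
#' mono-exponential decay -- and linear trapezoids otherwise (including
#' flat segments, avoiding 0/0).
#'
#' @param profile A [conc_profile()] with at least 2 points.
#' @param rule `"linear_up_log_down"` or `"linear"`.
#' @return AUC from the first to the last sampling time, ug*day/mL.
#' @examples
#' p <- conc_profile(c(0, 1), c(100, 50), species = "human", dose_per_kg = 1)
#' auc_trapezoid(p, "linear")            # 75
#' auc_trapezoid(p, "linear_up_log_down") # 50/ln(2) = 72.13
#' @export
auc_trapezoid <- function(profile, rule = c("linear_up_log_down", "linear")) {
  stopifnot(inherits(profile, "conc_profile"))
  rule <- match.arg(rule)
  t <- profile$time
  c1 <- profile$conc[-length(profile$conc)]
  c2 <- profile$conc[-1]
  if (length(t) < 2L)
    stop("need at least 2 points for AUC", call. = FALSE)
  dt <- diff(t)
  lin <- dt * (c1 + c2) / 2
  if (rule == "linear") return(sum(lin))
  down <- c2 < c1
  seg <- lin
  seg[down] <- dt[down] * (c1[down] - c2[down]) / log(c1[down] / c2[down])
  sum(seg)
}

#' Noncompartmental analysis of a concentration-time profile
#'
#' Computes AUC(0-last) by the trapezoidal rule, extrapolates to infinity
#' with `C_last / lambda_z`, and derives half-life and clearance:
#' `CL = dose_total / AUC_inf` (ug*day/mL = mg*day/L, dose in mg, so CL is
#' in L/day with no unit factor). No back-extrapolation to t = 0 is
#' performed: the AUC starts at the first sampled time.
#'
#' A warning is issued when the extrapolated fraction of the AUC exceeds
#' 20%.
#'
#' @param profile A [conc_profile()] with a known dose.
#' @param rule AUC rule, see [auc_trapezoid()].
#' @param lambda_strategy,n_points,min_points Passed to [fit_lambda_z()].
#' @return An object of class `nca_result`: list with `auc_last`,
#'   `auc_inf` (ug*day/mL), `lambda_z` (1/day), `thalf` (days),
#'   `clearance` (L/day), `extrap_fraction`, `n_lambda_points`, `r2_adj`.
#' @export
nca_summary <- function(profile, rule = c("linear_up_log_down", "linear"),
                        lambda_strategy = c("best_adj_r2", "fixed_n"),
                        n_points = 3L, min_points = 3L) {
  stopifnot(inherits(profile, "conc_profile"))
  rule <- match.arg(rule)
  lambda_strategy <- match.arg(lambda_strategy)
  if (length(profile$time) < 2L)
    stop("profile has fewer than 2 points", call. = FALSE)
  lz <- fit_lambda_z(profile, strategy = lambda_strategy,
                     n_points = n_points, min_points = min_points)
  auc_last <- auc_trapezoid(profile, rule)
  c_last <- profile$conc[length(profile$conc)]
  auc_inf <- auc_last + c_last / lz$lambda_z
  extrap <- (auc_inf - auc_last) / auc_inf
  if (extrap > 0.2)
    warning(sprintf("extrapolated AUC fraction %.1f%% exceeds 20%%",
                    100 * extrap), call. = FALSE)
  structure(
    list(auc_last = auc_last, auc_inf = auc_inf,
         lambda_z = lz$lambda_z, thalf = log(2) / lz$lambda_z,
         clearance = profile$dose_total / auc_inf,
         extrap_fraction = extrap,
         n_lambda_points = lz$points_used, r2_adj = lz$r2_adj),
    class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("<nca_result>\n")
  cat(sprintf("  AUC(0-last)  %12.6g ug*day/mL\n", x$auc_last))
  cat(sprintf("  AUC(0-inf)   %12.6g ug*day/mL (%.1f%% extrapolated)\n",
              x$auc_inf, 100 * x$extrap_fraction))
  cat(sprintf("  lambda_z     %12.6g 1/day (%d points, adj R2 %.4f)\n",
              x$lambda_z, x$n_lambda_points, x$r2_adj))
  cat(sprintf("  t1/2         %12.6g days\n", x$thalf))
  cat(sprintf("  CL           %12.6g L/day\n", x$clearance))
  invisible(x)
}

#' @export
as.data.frame.nca_result <- function(x, ...) {
  data.frame(auc_last = x$auc_last, auc_inf = x$auc_inf,
             lambda_z = x$lambda_z, thalf = x$thalf,
             clearance = x$clearance, extrap_fraction = x$extrap_fraction,
             n_lambda_points = x$n_lambda_points, r2_adj = x$r2_adj)
}
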