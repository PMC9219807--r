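#' Pair predicted and observed concentrations by time
#'
#' `"exact"` policy: a predicted point is paired with an observed point
#' when their times differ by at most `tol` (default 0.05 day); unmatched
#' points on either side are dropped with a message. `"interpolate"`
#' policy: the observed profile is log-linearly interpolated onto the
#' predicted times that fall strictly inside the observed time span
#' (no extrapolation).
#'
#' @param predicted A [conc_profile()] (typically a `predicted_profile`).
#' @param observed A [conc_profile()] of observed human data.
#' @param policy `"exact"` or `"interpolate"`.
#' @param tol Matching tolerance in days for the exact policy.
#' @return A data frame with columns `time`, `predicted`, `observed`.
#' @export
match_timepoints <- function(predicted, observed,
                             policy = c("exact", "interpolate"),
                             tol = 0.05) {
  stopifnot(inherits(predicted, "conc_profile"),
            inherits(observed, "conc_profile"))
  policy <- match.arg(policy)

  if (policy == "exact") {
    used_obs <- rep(FALSE, length(observed$time))
    pt <- numeric(0); pc <- numeric(0); oc <- numeric(0)
    for (i in seq_along(predicted$time)) {
      d <- abs(observed$time - predicted$time[i])
      d[used_obs] <- Inf
      j <- which.min(d)
      if (d[j] <= tol) {
        used_obs[j] <- TRUE
        pt <- c(pt, predicted$time[i])
        pc <- c(pc, predicted$conc[i])
        oc <- c(oc, observed$conc[j])
      }
    }
    dropped <- (length(predicted$time) - length(pt)) +
      sum(!used_obs)
    if (dropped > 0)
      message(sprintf("%d unmatched point(s) dropped", dropped))
    pairs <- data.frame(time = pt, predicted = pc, observed = oc)
  } else {
    inside <- predicted$time >= min(observed$time) &
      predicted$time <= max(observed$time)
    if (sum(!inside) > 0)
      message(sprintf("%d predicted point(s) outside the observed span dropped",
                      sum(!inside)))
    tt <- predicted$time[inside]
    obs_interp <- exp(stats::approx(observed$time, log(observed$conc),
                                    xout = tt)$y)
    pairs <- data.frame(time = tt, predicted = predicted$conc[inside],
                        observed = obs_interp)
  }
  if (nrow(pairs) == 0L)
    stop("no overlapping time points between predicted and observed profiles",
         call. = FALSE)
  pairs
}

#' Predicted/observed concentration ratios
#'
#' @param pairs Data frame from [match_timepoints()] (columns `predicted`,
#'   `observed`, both positive).
#' @return Numeric vector of ratios, one per pair.
#' @export
fold_ratios <- function(pairs) {
  stopifnot(all(c("predicted", "observed") %in% names(pairs)))
  if (any(pairs$predicted <= 0) || any(pairs$observed <= 0))
    stop("concentrations must be positive", call. = FALSE)
  pairs$predicted / pairs$observed
}

#' Average fold error
#'
#' The base-10 antilog of the mean log10 predicted/observed ratio --
#' i.e. the geometric mean of the ratios. 1.0 means no systematic
#' prediction error; values below/above 1 indicate systematic under-/
#' over-prediction.
#'
#' @param ratios Positive numeric vector of predicted/observed ratios.
#' @return Positive scalar.
#' @examples
#' afe(c(0.5, 2))  # 1
#' afe(c(2, 2))    # 2
#' @export
afe <- function(ratios) {
  if (length(ratios) == 0L)
    stop("ratios must be nonempty", call. = FALSE)
  if (any(ratios <= 0))
    stop("ratios must be positive", call. = FALSE)
  10^mean(log10(ratios))
}

#' Count ratios in the standard fold-error ranges
#'
#' The closed ranges \[0.5, 2\], \[0.5, 1.5\] and \[0.7, 1.3\] are counted
#' independently (they overlap and nest); `lt_0.5` and `gt_2` are strict.
#' Consequently `lt_0.5 + gt_2 + within_0.5_2` equals the number of ratios
#' and `within_0.7_1.3 <= within_0.5_1.5 <= within_0.5_2`.
#'
#' @param ratios Positive numeric vector.
#' @return Named integer vector with elements `lt_0.5`, `gt_2`,
#'   `within_0.5_2`, `within_0.5_1.5`, `within_0.7_1.3`.
#' @export
bin_fold_errors <- function(ratios) {
  if (length(ratios) == 0L)
    stop("ratios must be nonempty", call. = FALSE)
  c(lt_0.5         = sum(ratios < 0.5),
    gt_2           = sum(ratios > 2),
    within_0.5_2   = sum(ratios >= 0.5 & ratios <= 2),
    within_0.5_1.5 = sum(ratios >= 0.5 & ratios <= 1.5),
    within_0.7_1.3 = sum(ratios >= 0.7 & ratios <= 1.3))
}

#' Evaluate a predicted profile against observed data
#'
#' Composes [match_timepoints()], [fold_ratios()], [afe()] and
#' [bin_fold_errors()] into one report.
#'
#' @inheritParams match_timepoints
#' @return An object of class `evaluation_report`: list with `ratios`
#'   (data frame `time`, `ratio`), `n`, `afe`, `bin_counts`.
#' @examples
#' p <- conc_profile(c(1, 7, 14), c(100, 50, 10),
#'                   species = "human", dose_per_kg = 1)
#' evaluate_profiles(p, p)$afe  # exactly 1
#' @export
evaluate_profiles <- function(predicted, observed,
                              policy = c("exact", "interpolate"),
                              tol = 0.05) {
  pairs <- match_timepoints(predicted, observed, policy, tol)
  r <- fold_ratios(pairs)
  structure(
    list(ratios = data.frame(time = pairs$time, ratio = r),
         n = length(r), afe = afe(r), bin_counts = bin_fold_errors(r)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d, AFE = %.4g\n", x$n, x$afe))
  b <- x$bin_counts
  cat(sprintf("  <0.5: %d   [0.5,2]: %d   [0.5,1.5]: %d   [0.7,1.3]: %d   >2: %d\n",
              b[["lt_0.5"]], b[["within_0.5_2"]], b[["within_0.5_1.5"]],
              b[["within_0.7_1.3"]], b[["gt_2"]]))
  invisible(x)
}

#' Compare all eight preset methods against observed data
#'
#' Runs [predict_profile()] with every preset and evaluates each against
#' the observed human profile, producing a matrix of fold-error bin counts
#' plus AFE (one column per method, one row per bin/statistic).
#'
#' @param animal Animal [conc_profile()].
#' @param observed Observed human [conc_profile()].
#' @param human_dose_per_kg Human dose in mg/kg; defaults to the observed
#'   profile's per-kg dose.
#' @param human_weight Human weight in kg; defaults to the observed
#'   profile's weight.
#' @inheritParams match_timepoints
#' @return A data frame with a `quantity` column (`n`, the five bins, and
#'   `afe`) and one column per method I-VIII.
#' @export
compare_methods <- function(animal, observed,
                            human_dose_per_kg = observed$dose_per_kg,
                            human_weight = observed$body_weight,
                            policy = c("exact", "interpolate"),
                            tol = 0.05) {
  policy <- match.arg(policy)
  cols <- lapply(method_ids(), function(id) {
    pred <- predict_profile(animal, human_dose_per_kg, human_weight,
                            method_preset(id))
    rep <- evaluate_profiles(pred, observed, policy, tol)
    c(n = rep$n, rep$bin_counts, afe = rep$afe)
  })
  out <- data.frame(quantity = names(cols[[1]]))
  for (i in seq_along(cols)) out[[method_ids()[i]]] <- unname(cols[[i]])
  out
}
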