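#' Survival percentage of a selection pool
#'
#' `100 * survivors / total`, half-up rounded to one decimal, matching
#' the convention used for reported pool survival (e.g. 65 of 1,303 is
#' 5.0).
#'
#' @param survivors,total non-negative counts, `survivors <= total`,
#'   `total > 0`.
#' @return Percentage with one decimal.
#' @examples
#' survival_percent(65, 1303)   # 5.0
#' survival_percent(693, 2817)  # 24.6
#' @export
survival_percent <- function(survivors, total) {
  if (any(total <= 0)) stop("total must be > 0")
  if (any(survivors < 0) || any(survivors > total))
    stop("need 0 <= survivors <= total")
  floor(1000 * survivors / total + 0.5) / 10
}

#' Impute death times from periodic counts
#'
#' In a timed mortality assay, dead animals are counted periodically
#' rather than observed continuously. Each death recorded between
#' consecutive counting times t_k and t_{k+1} is assigned the midpoint
#' (t_k + t_{k+1}) / 2; deaths at the first count are assigned the
#' midpoint of (0, t_1). Animals alive at the last count are censored
#' at that time.
#'
#' @param times strictly increasing observation times (minutes).
#' @param cumulative_dead non-decreasing cumulative dead count at each
#'   time.
#' @param final_alive animals still alive at the last count.
#' @return Data frame `time`, `status` (1 = death, 0 = censored), one
#'   row per individual.
#' @examples
#' impute_death_times(c(60, 120), c(0, 3), final_alive = 10)
#' @export
impute_death_times <- function(times, cumulative_dead, final_alive = 0) {
  if (length(times) != length(cumulative_dead) || length(times) == 0)
    stop("times and cumulative_dead must have equal positive length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(cumulative_dead < 0) || any(diff(cumulative_dead) < 0))
    stop("cumulative dead counts must be non-negative and non-decreasing")
  if (final_alive < 0) stop("final_alive must be >= 0")
  new_dead <- diff(c(0, cumulative_dead))
  mid <- (c(0, head(times, -1)) + times) / 2
  out <- data.frame(
    time = c(rep(mid, new_dead), rep(tail(times, 1), final_alive)),
    status = rep(c(1L, 0L), c(sum(new_dead), final_alive)))
  out
}

#' Welch's unequal-variance t-test
#'
#' The two-sided t statistic with Welch-Satterthwaite degrees of
#' freedom, computed from the closed forms
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` and
#' `df = (s2x/nx + s2y/ny)^2 / ((s2x/nx)^2/(nx-1) + (s2y/ny)^2/(ny-1))`.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return `list(t, df, p)`.
#' @examples
#' welch_t(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs size >= 2")
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = nx + ny - 2, p = 1))
    stop("both samples have zero variance with unequal means")
  }
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
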