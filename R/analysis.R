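# Post-processing: exponential decay fitting, dwell-time maps over the
# (CaN, CaMKII) plane, and protocol sweeps.

#' Fit a single-exponential decay
#'
#' Least-squares fit of `y = a * exp(-t * b)` to a trace (after optional
#' baseline subtraction), reporting the decay time constant `tau = 1/b`.
#'
#' @param time,value Trace samples; `time` in seconds, start of the fitting
#'   window at the first sample.
#' @param baseline Baseline handling: `"tail"` subtracts the mean of the last
#'   5% of samples, `"none"` fits the raw trace, or a number to subtract.
#' @return List with `tau` (s), `a`, `b`, and `rss` (residual sum of squares,
#'   normalised by the squared amplitude).
#' @examples
#' t <- seq(0, 5, 0.01)
#' fit_decay(t, 3 * exp(-t / 0.8))$tau
#' @export
fit_decay <- function(time, value, baseline = "tail") {
  stopifnot(length(time) == length(value), length(time) >= 5)
  o <- order(time)
  time <- time[o]; value <- value[o]
  b0 <- if (identical(baseline, "tail")) {
    mean(value[time >= stats::quantile(time, 0.95)])
  } else if (identical(baseline, "none")) 0 else as.numeric(baseline)
  y <- value - b0
  t0 <- time - time[1]
  amp <- y[1]
  if (!is.finite(amp) || amp <= 0) stop("trace is not positive at the window start")
  # log-linear start values over the clearly positive part
  pos <- y > 0.05 * amp
  if (sum(pos) < 3) stop("trace decays too fast to fit on this grid")
  lf <- stats::lm(log(y[pos]) ~ t0[pos])
  b_start <- -unname(stats::coef(lf)[2])
  if (!is.finite(b_start) || b_start <= 0) {
    stop("trace does not decay: fitted rate is non-positive")
  }
  fit <- tryCatch(
    suppressWarnings(stats::nls(y ~ a * exp(-t0 * b),
               start = list(a = exp(unname(stats::coef(lf)[1])), b = b_start),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    a_hat <- exp(unname(stats::coef(lf)[1])); b_hat <- b_start
    rss <- sum((y - a_hat * exp(-t0 * b_hat))^2)
  } else {
    co <- stats::coef(fit)
    a_hat <- unname(co["a"]); b_hat <- unname(co["b"])
    rss <- sum(stats::resid(fit)^2)
  }
  span <- max(t0) - min(t0)
  if (b_hat <= 0 || 1 / b_hat > 100 * span) {
    stop("trace does not decay: fitted rate is non-positive or negligible")
  }
  list(tau = 1 / b_hat, a = a_hat, b = b_hat,
       rss = rss / max(a_hat^2, .Machine$double.eps))
}

#' Mean dwell-time map over the (CaN, CaMKII) plane
#'
#' Two-dimensional histogram of the time enzyme-activity orbits spend in each
#' bin of the (CaN, CaMKII) plane, averaged across samples. The total mass of
#' the map equals the mean trajectory duration.
#'
#' @param activity Data frame with columns `sample`, `time`, `can`, `camkii`
#'   (e.g. the trajectory of [simulate_synapse()]).
#' @param bins Number of bins per axis.
#' @param can_range,camkii_range Axis limits (uM); defaults cover the data.
#' @return Tibble with `can`, `camkii` (bin centres) and `time_s` (mean dwell
#'   time per bin, s); empty bins omitted.
#' @export
dwell_map <- function(activity, bins = 40,
                      can_range = NULL, camkii_range = NULL) {
  stopifnot(all(c("time", "can", "camkii") %in% names(activity)))
  if (!"sample" %in% names(activity)) activity$sample <- 1L
  if (is.null(can_range)) can_range <- range(activity$can)
  if (is.null(camkii_range)) camkii_range <- range(activity$camkii)
  xb <- seq(can_range[1], can_range[2], length.out = bins + 1)
  yb <- seq(camkii_range[1], camkii_range[2], length.out = bins + 1)
  n_samples <- length(unique(activity$sample))
  activity |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(dt = c(diff(.data$time), 0)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      ix = pmin(pmax(findInterval(.data$can, xb, all.inside = TRUE), 1L), bins),
      iy = pmin(pmax(findInterval(.data$camkii, yb, all.inside = TRUE), 1L), bins)
    ) |>
    dplyr::group_by(.data$ix, .data$iy) |>
    dplyr::summarise(time_s = sum(.data$dt) / n_samples, .groups = "drop") |>
    dplyr::mutate(
      can = (xb[.data$ix] + xb[.data$ix + 1L]) / 2,
      camkii = (yb[.data$iy] + yb[.data$iy + 1L]) / 2
    ) |>
    dplyr::select("can", "camkii", "time_s")
}

#' Sweep a protocol family over one or two axes
#'
#' Runs [simulate_synapse()] over a grid of protocol/condition variants and
#' collects the mean weight change per cell. Cell seeds are derived from the
#' cell index, so results are invariant to sweep order.
#'
#' @param grid A data frame; each row is one cell. Recognised columns:
#'   `protocol` (spec string passed to [build_protocol()]) and any named
#'   arguments of [experimental_conditions()] (e.g. `age`, `ca_o`).
#' @param n_samples Samples per cell.
#' @param seed Base seed.
#' @param ... Passed to [simulate_synapse()].
#' @return The grid with columns `mean_weight`, `median_weight`, `q25`, `q75`.
#' @export
sweep_protocols <- function(grid, n_samples = 10, seed = 1, ...) {
  stopifnot(is.data.frame(grid), "protocol" %in% names(grid))
  cond_args <- intersect(names(grid), names(formals(experimental_conditions)))
  res <- purrr::map(seq_len(nrow(grid)), function(i) {
    cond <- do.call(experimental_conditions,
                    as.list(grid[i, cond_args, drop = FALSE]))
    sim <- simulate_synapse(build_protocol(grid$protocol[i]), cond,
                            n_samples = n_samples,
                            seed = seed + 104729L * i, ...)
    w <- tidy(sim)$weight
    tibble::tibble(mean_weight = mean(w), median_weight = stats::median(w),
                   q25 = unname(stats::quantile(w, 0.25)),
                   q75 = unname(stats::quantile(w, 0.75)))
  })
  dplyr::bind_cols(tibble::as_tibble(grid), dplyr::bind_rows(res))
}
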