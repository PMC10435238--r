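# Simulation driver: presynaptic stage, event assembly, C++ engine calls,
# result containers.

#' Simulate the synapse model under a stimulation protocol
#'
#' Runs the full hybrid stochastic model: the presynaptic vesicle/release
#' stage is simulated first (it depends only on the protocol and conditions),
#' its release events drive the postsynaptic electrical, calcium and enzyme
#' dynamics, and the geometric readout accumulates the plasticity outcome.
#' Samples are independent replicas with per-sample derived seeds.
#'
#' @param protocol A [build_protocol()] protocol.
#' @param conditions A [experimental_conditions()] object.
#' @param n_samples Number of independent samples.
#' @param seed Integer seed; every source of randomness derives from it.
#' @param relax Simulated time (s) after the last stimulus, letting enzymes
#'   decay and slow plasticity transitions complete.
#' @param duration Total simulated time (s); default `stimulation + relax`.
#' @param output_dt Trajectory sampling interval (s).
#' @param force_release Force a release on every presynaptic spike
#'   (uncaging-style stimulation; suppresses GABA co-release).
#' @param params Optional pre-built [synapse_params()]; default built from
#'   `conditions`.
#' @param control Optional named list overriding engine controls
#'   (`dt_stim`, `dt_ap`, `dt_relax`, `warmup_det`, `warmup_stoch`).
#' @return A `synapse_sim` object: list with `trajectory` (tibble: `sample`,
#'   `time`, voltages, calcium, open counts, enzyme activities, readout
#'   state), `outcomes` (tibble: per-sample `weight` (%), `max_ca`,
#'   `max_v_sp`), `pulse_peaks` (per-BaP voltage peaks), `presyn` (per-spike
#'   release records), plus the protocol/conditions/params used.
#' @examples
#' \donttest{
#' sim <- simulate_synapse(build_protocol("1Pre1Post10, 5 at 5 Hz"),
#'                         experimental_conditions(), n_samples = 2, seed = 1,
#'                         relax = 5)
#' glance(sim)
#' }
#' @export
simulate_synapse <- function(protocol, conditions = experimental_conditions(),
                             n_samples = 1, seed = NULL, relax = 100,
                             duration = NULL, output_dt = 0.01,
                             force_release = FALSE, params = NULL,
                             control = list()) {
  stopifnot(inherits(protocol, "synapse_protocol"), n_samples >= 1)
  if (is.null(params)) params <- synapse_params(conditions)
  ctrl <- utils::modifyList(list(
    dt_stim = 5e-5, dt_ap = 1e-5, dt_relax = 5e-4,
    warmup_det = 150, warmup_stoch = 5, record_peaks = TRUE
  ), control)

  trajs <- vector("list", n_samples)
  outs <- vector("list", n_samples)
  peaks <- vector("list", n_samples)
  presyns <- vector("list", n_samples)

  for (i in seq_len(n_samples)) {
    if (!is.null(seed)) set.seed((seed + (i - 1) * 1000003) %% 2147483647)
    run <- run_one_sample(protocol, conditions, params, ctrl,
                          relax, duration, output_dt, force_release)
    trajs[[i]] <- dplyr::mutate(run$traj, sample = i, .before = 1)
    peaks[[i]] <- if (nrow(run$peaks)) dplyr::mutate(run$peaks, sample = i, .before = 1)
    presyns[[i]] <- dplyr::mutate(run$presyn, sample = i, .before = 1)
    outs[[i]] <- tibble::tibble(sample = i, weight = run$weight,
                                max_ca = run$max_ca, max_v_sp = run$max_v_sp,
                                counts_conserved = run$conserved,
                                neg_ca_events = run$neg_ca)
  }
  structure(list(
    trajectory = dplyr::bind_rows(trajs),
    outcomes = dplyr::bind_rows(outs),
    pulse_peaks = dplyr::bind_rows(peaks),
    presyn = dplyr::bind_rows(presyns),
    protocol = protocol, conditions = conditions, params = params,
    seed = seed, control = ctrl
  ), class = "synapse_sim")
}

run_one_sample <- function(protocol, conditions, params, ctrl,
                           relax, duration, output_dt, force_release) {
  # per-sample NMDAr subunit split (ratio noise flips ~1 receptor)
  noise <- if ("nmda" %in% conditions$deterministic_sources) 0 else
    stats::rnorm(1, 0, 0.05)
  counts <- nmda_subunit_counts(conditions$age, noise, params$n_nmda)

  presyn <- presyn_simulate(protocol, conditions, params,
                            force_release = force_release)
  evoked <- attr(presyn, "evoked_ap_times")
  post <- sort(c(protocol$post_times, evoked))

  rel <- presyn[presyn$released, , drop = FALSE]
  ev <- matrix(numeric(0), ncol = 3)
  if (nrow(rel)) {
    glu_on <- cbind(rel$time, 1, rel$glu)
    glu_off <- cbind(rel$time + params$glu_width, 1, -rel$glu)
    ev <- rbind(ev, glu_on, glu_off)
    if (!force_release) {
      ev <- rbind(ev, cbind(rel$time, 2, rel$glu),
                  cbind(rel$time + params$glu_width, 2, -rel$glu))
    }
  }
  if (length(post)) {
    ev <- rbind(ev, cbind(post, 3, params$i_amp),
                cbind(post + params$delta_inj, 3, -params$i_amp))
  }
  all_spk <- c(protocol$pre_times, post)
  stim_end <- if (length(all_spk)) max(all_spk) + 0.1 else 0
  if (is.null(duration)) duration <- stim_end + relax
  ev <- ev[ev[, 1] < duration, , drop = FALSE]
  ev <- ev[order(ev[, 1]), , drop = FALSE]

  control <- list(duration = duration, dt_stim = ctrl$dt_stim, dt_ap = ctrl$dt_ap,
                  dt_relax = ctrl$dt_relax, output_dt = output_dt,
                  warmup_det = ctrl$warmup_det, warmup_stoch = ctrl$warmup_stoch,
                  post_times = post, stim_end = stim_end,
                  record_peaks = isTRUE(ctrl$record_peaks))
  res <- engine_run(params, ev, control, counts[["glun2a"]], counts[["glun2b"]],
                    conditions$deterministic_sources)
  traj <- tibble::as_tibble(res$trajectory)
  pk <- res$pulse_peaks
  pk <- if (nrow(pk)) tibble::as_tibble(pk) else
    tibble::tibble(time = numeric(), v_soma_peak = numeric(),
                   v_dend_peak = numeric(), v_sp_peak = numeric())
  list(traj = traj, peaks = pk, presyn = presyn,
       weight = res$weight_change, max_ca = res$max_ca,
       max_v_sp = res$max_v_sp, conserved = res$counts_conserved,
       neg_ca = res$neg_ca_events)
}

#' @export
print.synapse_sim <- function(x, ...) {
  cat("<synapse_sim> ", x$protocol$name, "\n", sep = "")
  print(x$conditions)
  w <- x$outcomes$weight
  cat(sprintf("  samples: %d, weight change: mean %.1f%%, median %.1f%%\n",
              length(w), mean(w), stats::median(w)))
  invisible(x)
}

#' Run a batch of independent samples for one protocol
#'
#' Convenience wrapper around [simulate_synapse()] that emphasises the
#' sampling dimension; identical machinery.
#'
#' @inheritParams simulate_synapse
#' @return A `synapse_sim` object.
#' @export
batch_run <- function(protocol, conditions = experimental_conditions(),
                      n_samples = 100, seed = 1, ...) {
  simulate_synapse(protocol, conditions, n_samples = n_samples, seed = seed, ...)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-sample plasticity outcomes
#'
#' @param x A `synapse_sim` object.
#' @param ... Unused.
#' @return Tibble with one row per sample: `weight` (%), `max_ca` (uM),
#'   `max_v_sp` (mV).
#' @export
tidy.synapse_sim <- function(x, ...) x$outcomes

#' One-row summary of a simulation batch
#'
#' @param x A `synapse_sim` object.
#' @param ... Unused.
#' @return Tibble with `n_samples`, `mean_weight`, `median_weight`, `q25`,
#'   `q75`, `sd_weight`, `mean_peak_ca`.
#' @export
glance.synapse_sim <- function(x, ...) {
  w <- x$outcomes$weight
  tibble::tibble(
    n_samples = length(w), mean_weight = mean(w),
    median_weight = stats::median(w),
    q25 = unname(stats::quantile(w, 0.25)), q75 = unname(stats::quantile(w, 0.75)),
    sd_weight = stats::sd(w), mean_peak_ca = mean(x$outcomes$max_ca))
}
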