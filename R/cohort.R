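#' Bystander adenosines within the guide window
#'
#' @param ref An [amplicon_ref()].
#' @return 1-based positions of the guide-window adenosines other than the
#'   target (the duplex-exposed bystander candidates).
#' @export
guide_window_bystanders <- function(ref) {
  stopifnot(inherits(ref, "amplicon_ref"))
  a <- ref$adenosine_positions
  setdiff(
    a[a >= ref$guide_window[1] & a <= ref$guide_window[2]],
    ref$target_pos
  )
}

#' Simulator configuration pegged to observed editing rates
#'
#' Builds a [sim_config()] whose expected *observed* rates (what the
#' quantification pipeline estimates, sequencing-error floor included)
#' equal the requested on-target and bystander rates. The engagement
#' probability is set to the calibrated on-target probability (engaged
#' transcripts always carry the target edit), and bystander probabilities
#' are scaled conditional on engagement so their marginal rates match.
#'
#' @param ref An [amplicon_ref()].
#' @param on_target_rate Desired expected observed on-target rate
#'   (fraction). 0 gives an unengaged (control) sample.
#' @param bystander_rates Named numeric vector (position -> desired
#'   expected observed marginal rate) for bystander sites; requires
#'   `on_target_rate > 0`.
#' @param n_reads,seq_error,seed,... Passed to [sim_config()].
#' @return A [sim_config()].
#' @export
cohort_sim_config <- function(ref, on_target_rate, bystander_rates = numeric(0),
                              n_reads = 20000L, seq_error = 0.001,
                              seed = 1L, ...) {
  e <- if (on_target_rate > 0) {
    calibrate_edit_prob(on_target_rate, seq_error)
  } else {
    0
  }
  q <- numeric(0)
  if (length(bystander_rates)) {
    if (e <= 0) {
      stop("bystander rates require a positive on-target rate (engagement)")
    }
    p_marg <- calibrate_edit_prob(bystander_rates, seq_error)
    q <- p_marg / e
    if (any(q > 1)) {
      stop("bystander rate too high for the given engagement probability")
    }
    names(q) <- names(bystander_rates)
  }
  sim_config(
    n_reads = n_reads,
    engagement_prob = e,
    on_target_prob_given_engaged = 1,
    bystander_probs = q,
    seq_error = seq_error,
    seed = seed,
    ...
  )
}

#' Simulate and quantify a replicate cohort
#'
#' Generates `n_replicates` independent samples from the same generative
#' condition (replicate seeds are `seed + 0:(n-1)`) and runs each through
#' the quantification pipeline.
#'
#' @inheritParams cohort_sim_config
#' @param n_replicates Number of biological replicates (e.g. eyes).
#' @param condition Condition label used for sample ids.
#' @param keep_calls Keep per-read call matrices (see [quantify_sample()]).
#' @return A list of `edit_sample` objects, one per replicate.
#' @export
simulate_cohort <- function(ref, n_replicates = 6L, on_target_rate = 0,
                            bystander_rates = numeric(0), n_reads = 20000L,
                            seq_error = 0.001, seed = 1L,
                            condition = "condition", keep_calls = FALSE,
                            ...) {
  lapply(seq_len(n_replicates), function(i) {
    cfg <- cohort_sim_config(
      ref, on_target_rate, bystander_rates,
      n_reads = n_reads, seq_error = seq_error, seed = seed + i - 1L, ...
    )
    reads <- simulate_reads(ref, cfg)
    quantify_sample(
      reads, ref,
      sample_id = sprintf("%s_rep%d", condition, i),
      keep_calls = keep_calls
    )
  })
}
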