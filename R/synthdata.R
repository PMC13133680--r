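#' Cohort specification for the synthetic EEG generator
#'
#' Describes a two-class (mild/moderate) motor-imagery-like EEG cohort.
#' The class difference is planted exclusively as band-limited
#' phase-coupling topology: each class carries a configurable set of
#' coupled channel rings in one frequency band, so that phase-locking
#' connectivity (and hence the H1 persistent homology of its distance
#' matrix) differs between classes while everything else is exchangeable
#' noise.
#'
#' @param n_mild,n_moderate Subjects per class (defaults 33 and 17).
#' @param n_trials Trials per subject (default 20).
#' @param trial_seconds Trial duration in seconds (default 8).
#' @param fs Sampling rate in Hz (default 250).
#' @param effect List describing the planted effect: `band` (band name),
#'   `kappa` in `[0, 1]` (coupling strength; 0 removes the effect),
#'   `rings_mild` / `rings_moderate` (lists of character vectors of
#'   channel labels, each vector one coupled ring).
#' @param noise_sd Background white-noise standard deviation in microvolts.
#' @param montage Channel labels (default [default_montage()]).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_mild = 33, n_moderate = 17, n_trials = 20,
                        trial_seconds = 8, fs = 250,
                        effect = planted_effect(), noise_sd = 1,
                        montage = default_montage(), seed = 42) {
  spec <- list(n_mild = as.integer(n_mild), n_moderate = as.integer(n_moderate),
               n_trials = as.integer(n_trials),
               trial_seconds = as.numeric(trial_seconds), fs = as.numeric(fs),
               effect = effect, noise_sd = as.numeric(noise_sd),
               montage = as.character(montage), seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' Default planted phase-coupling effect
#'
#' Mild subjects carry one coupled 4-channel frontal ring in the gamma
#' band; moderate subjects carry that ring plus a second, larger
#' centro-parietal ring, so the two classes differ in the number and size
#' of gamma-band cycles.
#'
#' @param band Band carrying the coupling (default `"gamma"`).
#' @param kappa Coupling strength in `[0, 1]`.
#' @param rings_mild,rings_moderate Lists of channel-label rings.
#' @return Effect descriptor list.
#' @export
planted_effect <- function(band = "gamma", kappa = 0.8,
                           rings_mild = list(c("F3", "Fz", "F4", "FCz")),
                           rings_moderate = list(
                             c("F3", "Fz", "F4", "FCz"),
                             c("CP3", "CPz", "CP4", "Pz", "Cz"))) {
  list(band = band, kappa = kappa,
       rings_mild = rings_mild, rings_moderate = rings_moderate)
}

validate_cohort_spec <- function(spec) {
  if (spec$n_mild <= 0 || spec$n_moderate <= 0 || spec$n_trials <= 0)
    stop("all cohort counts must be positive", call. = FALSE)
  if (spec$trial_seconds <= 0) stop("trial_seconds must be positive",
                                    call. = FALSE)
  if (spec$fs < 80) stop("fs must be >= 80 Hz", call. = FALSE)
  ef <- spec$effect
  if (!ef$band %in% names(EEG_BANDS))
    stop("unknown effect band '", ef$band, "'", call. = FALSE)
  if (!is.numeric(ef$kappa) || ef$kappa < 0 || ef$kappa > 1)
    stop("kappa must lie in [0, 1]", call. = FALSE)
  ring_chans <- unlist(c(ef$rings_mild, ef$rings_moderate))
  missing <- setdiff(ring_chans, spec$montage)
  if (length(missing))
    stop("ring channels not in montage: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(spec)
}

# One trial's worth of planted ring oscillations. Ring channel i receives
# the sum of components i and i+1 (mod ring length): adjacent channels
# share one narrowband component, non-adjacent none, so phase locking is
# high exactly along the ring's edges.
ring_oscillation <- function(rings, montage, n_samples, fs, band, amp) {
  out <- matrix(0, length(montage), n_samples)
  tt <- (seq_len(n_samples) - 1) / fs
  lims <- EEG_BANDS[[band]]
  for (ring in rings) {
    L <- length(ring)
    freqs <- runif(L, lims[1] + 1, lims[2] - 1)
    phases <- runif(L, 0, 2 * pi)
    comps <- vapply(seq_len(L),
                    function(k) sin(2 * pi * freqs[k] * tt + phases[k]),
                    numeric(n_samples))
    idx <- match(ring, montage)
    for (i in seq_len(L)) {
      nxt <- if (i == L) 1L else i + 1L
      out[idx[i], ] <- out[idx[i], ] + amp * (comps[, i] + comps[, nxt])
    }
  }
  out
}

#' Generate a synthetic EEG cohort
#'
#' Draws `n_mild + n_moderate` recordings. Each recording is white
#' Gaussian background noise with, per trial, class-specific coupled
#' channel rings in the effect band (see [planted_effect()]). With
#' `kappa = 0` the classes are exchangeable. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return List of [eeg_recording()] objects; mild subjects first
#'   (ids `"1"`..), then moderate.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_local_seed(spec$seed, {
    n_ch <- length(spec$montage)
    trial_len <- round(spec$trial_seconds * spec$fs)
    n_samples <- spec$n_trials * trial_len
    onsets <- seq(1L, by = trial_len, length.out = spec$n_trials)
    amp <- 1.5 * spec$effect$kappa * spec$noise_sd
    labels <- c(rep("mild", spec$n_mild), rep("moderate", spec$n_moderate))
    lapply(seq_along(labels), function(s) {
      lab <- labels[s]
      nihss <- if (lab == "mild") sample(1:4, 1) else sample(5:11, 1)
      data <- matrix(rnorm(n_ch * n_samples, 0, spec$noise_sd), n_ch,
                     n_samples)
      rings <- if (lab == "mild") spec$effect$rings_mild else
        spec$effect$rings_moderate
      if (amp > 0 && length(rings)) {
        for (tr in seq_len(spec$n_trials)) {
          cols <- (onsets[tr]):(onsets[tr] + trial_len - 1L)
          data[, cols] <- data[, cols] +
            ring_oscillation(rings, spec$montage, trial_len, spec$fs,
                             spec$effect$band, amp)
        }
      }
      eeg_recording(subject_id = as.character(s), data = data,
                    channel_labels = spec$montage, fs = spec$fs,
                    trial_onsets = onsets, label = lab, nihss = nihss)
    })
  })
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The statistic is the smaller of
#' the two one-sided U statistics (so complete separation gives U = 0,
#' the value clinical tables report); the two-sided p-value uses the
#' normal approximation with the tie correction.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List with `u_statistic` and `p`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(group_a); n2 <- length(group_b); n <- n1 + n2
  r <- rank(c(group_a, group_b))
  r1 <- sum(r[seq_len(n1)])
  u1 <- n1 * n2 + n1 * (n1 + 1) / 2 - r1
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- table(c(group_a, group_b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(u_statistic = u, p = 1))
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  list(u_statistic = u, p = min(1, 2 * pnorm(-abs(z))))
}
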