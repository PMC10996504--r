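# Shared fixtures built in code.

# deterministic toy schedule: n isolated presentations per modality,
# alternating with 15-s cross-modal spacing (no overlap exclusions)
toy_schedule <- function(n = 10, gap = 30, cs_plus = "tactile") {
  on_t <- 100 + gap * (seq_len(n) - 1)
  on_v <- on_t + gap / 2
  ev <- data.frame(
    onset_s = c(on_t, on_v),
    duration_s = 2,
    modality = rep(c("tactile", "visual"), each = n),
    rewarded = rep(c(cs_plus == "tactile", cs_plus == "visual"), each = n),
    reward_time_s = NA_real_
  )
  ev$reward_time_s[ev$rewarded] <- ev$onset_s[ev$rewarded] + 2
  stim_schedule(ev, task_phase = "full", cs_plus = cs_plus)
}

# lick times realizing given baseline/stimulus counts for one presentation
licks_for_counts <- function(n_base, n_stim, onset = 10, duration = 2) {
  c(
    if (n_base > 0) seq(onset - 1.9, onset - 0.2, length.out = n_base),
    if (n_stim > 0) seq(onset + 0.2, onset + duration - 0.1, length.out = n_stim)
  )
}
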