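# Shared fixtures, all built in code.

default_geom <- strand_geometry()
default_chain <- cell_chain_params()
default_tpl <- apec_template()

# a shortened protocol for fast orchestration tests (2 cycles)
short_protocol_args <- list(baseline_s = 2, n_cycles = 2, tail_s = 2)

# render a single-channel record of `n` beats with a fixed activation
# offset after each stimulus
render_beat_train <- function(n, offset = 0.01, noise_rms = 0,
                              quantize = FALSE, seed = NULL,
                              tpl = default_tpl, artifacts = FALSE) {
  stim <- (seq_len(n) - 1) * 0.4
  act <- data.frame(beat_index = seq_len(n), electrode = "III",
                    t_AT_s = stim + offset)
  rec <- render_record(act, tpl, duration = n * 0.4, stim_times = stim,
                       noise_rms = noise_rms,
                       stim_artifact_uV = if (artifacts) 1000 else 0,
                       dea_artifact_uV = if (artifacts) 500 else 0,
                       quantize = quantize, seed = seed)
  list(record = blank_intervals(rec), activation = act)
}
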