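# Shared fixtures: the published Monod&Sigmoid batch parameter set and the
# standard inoculation state.
p_ms <- vo_batch_params("monod_sigmoid")
p_monod <- vo_batch_params("monod")
p_sig <- vo_batch_params("sigmoid")
init_std <- vo_initial_state()

# a parameter set with no maintenance, for conservation checks
p_nomaint <- as_kinetic_params(replace(unclass(p_ms), c("m_s1", "m_s2"), 0))

final_row <- function(tr) tr[nrow(tr), ]
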