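# shared fixtures: the reference two-stage life cycle and a small
# three-stage cycle used for cross-engine checks
ref2 <- two_stage_example()
ref_vital <- ref2$vital
ref_history <- typical_life_history(
  fundamental_matrix(rebuild_matrix(ref_vital)), ref2$H
)

vital3 <- vital_rates(s_max = c(0.8, 0.9, 0.95), g = c(0.4, 0.3))

linear_series <- function(T0 = 10, total = 1.7, H = 60) {
  T0 + (total / 60) * seq_len(H)
}
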