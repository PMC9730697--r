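# Session-level cache for the replication experiments shared by several
# acceptance checks, so the expensive fits run once per test session.
.expCache <- new.env(parent = emptyenv())

# skewed-density recovery under the 6-3 Ramsay model, N = 1000, J = 30,
# rc-mode SAEM, 20 replications (the headline recovery experiment)
skewedRcExperiment <- function() {
  if (is.null(.expCache$rc))
    .expCache$rc <- recoveryExperiment("skewed", N = 1000, J = 30, R = 20,
                                       seed = 1, mode = "rc")
  .expCache$rc
}

# same generating conditions fitted with the density fixed at the standard
# normal (the mis-specified comparator), 10 replications
skewedNormalModeExperiment <- function() {
  if (is.null(.expCache$normal))
    .expCache$normal <- recoveryExperiment("skewed", N = 1000, J = 30,
                                           R = 10, seed = 1, mode = "normal")
  .expCache$normal
}
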