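# Evolved toy organisms are expensive; evolve each once per test run and
# cache for all downstream blocks.
.organisms <- new.env(parent = emptyenv())

evolved_stripe <- function(seed = 101L) {
  key <- paste0("stripe", seed)
  if (is.null(.organisms[[key]])) {
    cond <- toy_study_conditions("stripe")
    .organisms[[key]] <- evolve_nca(cond$pattern, cond$config, seed = seed)
  }
  .organisms[[key]]
}

evolved_face <- function(seed = 101L) {
  key <- paste0("face", seed)
  if (is.null(.organisms[[key]])) {
    cond <- toy_study_conditions("face")
    .organisms[[key]] <- evolve_nca(cond$pattern, cond$config, seed = seed)
  }
  .organisms[[key]]
}
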