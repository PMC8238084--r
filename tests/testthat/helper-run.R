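# One reduced-replication run of the full study grid (101 difference
# levels x 300 pairs x both approaches), computed once and shared by
# the tests that check study-scale quantities. 300 pairs per level keep
# Monte-Carlo error on aggregate proportions around a percentage point.

.run_cache <- new.env(parent = emptyenv())

reduced_run <- function() {
  if (is.null(.run_cache$res)) {
    .run_cache$res <- run_experiment(sim_config(diffs = 0:100, reps = 300,
                                                seed = 101))
  }
  .run_cache$res
}
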