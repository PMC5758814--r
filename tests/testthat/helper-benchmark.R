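# The full-scale synthetic benchmark (30 training / 10 test subjects,
# default bank and image size) is expensive; it is computed once per test
# run and shared by the evaluation-level tests.

benchmark_fixture <- function() fixture("benchmark", function()
  run_benchmark(face_spec(seed = 1), n_train = 30L, n_test = 10L))

# second, independently drawn cohort evaluated with the benchmark's models
extra_cohort_fixture <- function() fixture("extra_cohort", function() {
  spec <- face_spec(seed = 2)
  pop <- generate_population(spec, 10)
  lapply(pop, prepare_subject)
})
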