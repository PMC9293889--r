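# shared small fixtures, built once per test run

tiny_config <- function(...) {
  sim_config(n_genes = 40, depth = 2e5, seed = 7, ...)
}

# cached small ground truth reused by read-only tests
.tiny_truth <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- simulate_truth(tiny_config())
    val
  }
})
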