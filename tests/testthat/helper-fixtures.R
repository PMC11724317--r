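# Small synthetic fixtures shared across test files (built once per run).

two_state_frames <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- conformer_truth(states = list(
        "anti-anti" = list(chi = c(200, 200), hbonds = 2),
        "syn-anti" = list(chi = c(60, 200), hbonds = 1)),
        schedule = c("anti-anti" = 0.7, "syn-anti" = 0.3),
        jitter_sd = 0.05)
      cache <<- gen_duplex_frames(tr, n_frames = 300, seed = 7)
    }
    cache
  }
})
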