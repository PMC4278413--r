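# Shared fixtures, computed once per test run and reused across files.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

# clocks for the four standard regimes (surrogate mode)
std_clocks <- function(duration = 72) {
  cached(paste0("clocks_", duration), {
    regs <- standard_regimes()
    setNames(lapply(regs, simulate_clock, duration = duration), names(regs))
  })
}

# the full default selection run (seed 1), shared by the acceptance tests
full_run <- function() {
  cached("full_run", {
    run_selection(run_config(seed = 1,
                             out_dir = file.path(tempdir(), "cbfclock-full")))
  })
}

top_label <- "EC↓:TOC1↓:LHY/CCA1↑"

# a mid-complexity reference parameter set used by several tests
ref_params <- function(arch, K = 0.3, v_max = 1, d = 1.5) {
  cbf_params(v_max, setNames(rep(K, length(c(arch$activators,
                                             arch$repressors))),
                             c(arch$activators, arch$repressors)), d)
}
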