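# Shared fixtures: small pools of random valid parameter sets, drawn once per
# test run under fixed seeds.
valid_pool <- local({
  cache <- NULL
  function(n = 30, seed = 101) {
    if (is.null(cache)) cache <<- sample_parameters(n, seed = seed)
    cache
  }
})

# terminal state of a trajectory as a plain numeric vector
terminal_state <- function(traj) pmax(as.numeric(traj[nrow(traj), -1]), 0)

# drive values where a given branch exists, scanned on a fine grid
drives_where_exists <- function(label, params, n = 400) {
  d <- seq(0.002, 0.998, length.out = n)
  d[vapply(d, function(dd)
    branch_exists(label, s_from_drive(dd, params$S_half), params), logical(1))]
}
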