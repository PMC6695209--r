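# Shared helpers: small grids and cached baseline runs so the suite stays
# fast while every expectation still comes from a real solve.

quiet_geom <- function(...) suppressMessages(channel_geometry(...))

# Baseline 800-s trajectory, computed once per test run.
baseline_traj <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cascade(t_end = 800)
    cache
  }
})

last_row <- function(traj) traj[nrow(traj), ]

total_iia <- function(row) row$iia_free + row$es + row$gs

trapz <- function(t, v) sum(diff(t) * (v[-1] + v[-length(v)]) / 2)
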