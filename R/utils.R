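# Internal helpers shared across modules.

# Run `code` under a local RNG seed without touching global random state.
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Evaluate a trajectory data frame (columns time, value) at time t by linear
# interpolation. At duplicated times (dose instants) `convention` picks the
# pre-jump ("pre_dose") or post-jump ("instant") row.
traj_interp <- function(times, values, t, convention = c("pre_dose", "instant")) {
  convention <- match.arg(convention)
  n <- length(times)
  if (t < times[1L] - 1e-9 || t > times[n] + 1e-9)
    stop("evaluation time ", t, " outside trajectory span", call. = FALSE)
  exact <- which(abs(times - t) < 1e-9)
  if (length(exact))
    return(values[if (convention == "pre_dose") exact[1L] else exact[length(exact)]])
  i <- findInterval(t, times)
  i <- max(1L, min(i, n - 1L))
  w <- (t - times[i]) / (times[i + 1L] - times[i])
  values[i] * (1 - w) + values[i + 1L] * w
}

# Build the output grid for a half-open segment (t0, t1]: interior points of
# the global step grid plus the right boundary.
segment_grid <- function(t0, t1, dt) {
  eps <- 1e-9
  first <- ceiling((t0 + eps) / dt) * dt
  pts <- if (first < t1 - eps) seq(first, t1 - eps, by = dt) else numeric(0)
  pts <- pts[pts > t0 + eps]
  c(pts, t1)
}
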