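# Shared small-scale fixtures, all generated in code.

quiet_scene <- function(...) scene_config(noise_sd = 0, ...)

# a short tracked waggle snippet plus its truth, deterministic
fixture_snippet <- function(orientation = 37, n_frames = 58, noise_sd = 3,
                            seed = 42, ...) {
  render_run_snippet(scene_config(noise_sd = noise_sd, ...), orientation,
                     n_frames, seed = seed)
}

# brute-force single-linkage clustering at threshold h (union-find)
oracle_single_linkage <- function(pts, h) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sqrt(sum((pts[i, ] - pts[j, ])^2)) <= h) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 0L)
}

# circular mean via complex arithmetic (independent of package code)
oracle_circ_mean <- function(deg) {
  (Arg(sum(complex(argument = deg * pi / 180))) * 180 / pi) %% 360
}

same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
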