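# Shared, lazily cached windup simulations.  Several test files compare the
# same reference runs; each distinct configuration is simulated once per
# session.
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, cfg, protocol = stim_protocol()) {
  if (!exists(key, .sim_cache)) {
    assign(key, run_windup(cfg, protocol), .sim_cache)
  }
  get(key, .sim_cache)
}

cached_summary <- function(key, cfg, protocol = stim_protocol()) {
  windup_summary(cached_sim(key, cfg, protocol))
}

ctrl_sim <- function() cached_sim("control", scenario_config())

homo_cfg <- function(g, ...) {
  scenario_config(asic_variant = "homomeric", g_asic_ns = g, ...)
}
het_cfg <- function(g, ...) {
  scenario_config(asic_variant = "heteromeric", g_asic_ns = g, ...)
}

cached_sweep_moderate <- function() {
  if (!exists("sweep_mod", .sim_cache)) {
    assign("sweep_mod",
           conductance_sweep("homomeric", c(0, 0.05, 0.2)), .sim_cache)
  }
  get("sweep_mod", .sim_cache)
}

cached_scan_default <- function() {
  if (!exists("scan_default", .sim_cache)) {
    assign("scan_default",
           parameter_scan(q_grid = 0.3, tau_grid = 0.1, ph_n_stims = 100),
           .sim_cache)
  }
  get("scan_default", .sim_cache)
}

# centered moving average used to judge windup-curve shape
smooth_counts <- function(x, k = 5) {
  n <- length(x)
  half <- k %/% 2
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - half):min(n, i + half)]), numeric(1))
}
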