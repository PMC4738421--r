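# Seed-averaged metrics for scenarios that include the stochastic
# external-damage process.
seed_average <- function(name, seeds = 1:10, overrides = list()) {
  runs <- lapply(seeds, function(s) {
    run_scenario(name, c(overrides, list(seed = s)))$metrics
  })
  out <- runs[[1L]]
  for (col in c("qbar", "sigma_q", "p0", "nprob")) {
    out[[col]] <- rowMeans(vapply(runs, `[[`, numeric(nrow(out)), col))
  }
  out
}

final_row <- function(metrics) metrics[nrow(metrics), ]

# The 100000-step seed averages are shared by several acceptance blocks;
# compute each once per test run.
.seed_avg_cache <- new.env(parent = emptyenv())

cached_average <- function(name, seeds = 1:10, overrides = list()) {
  key <- paste(name, paste(seeds, collapse = ","),
               paste(names(overrides), unlist(overrides), collapse = ";"))
  if (!exists(key, envir = .seed_avg_cache)) {
    assign(key, seed_average(name, seeds, overrides), envir = .seed_avg_cache)
  }
  get(key, envir = .seed_avg_cache)
}
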