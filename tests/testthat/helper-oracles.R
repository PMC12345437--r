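# Independent oracles and small fixture builders used across the suite.

# Brute-force binomial pmf: enumerate all 2^n outcome sequences of n
# independent attempts and accumulate the probability of each success
# count. Deliberately avoids dbinom/choose so it is an independent check
# of the litter-count model.
enumerate_binomial <- function(p, n) {
  probs <- rep(0, n + 1)
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    k <- sum(bits)
    probs[k + 1] <- probs[k + 1] + prod(ifelse(bits == 1, p, 1 - p))
  }
  probs
}

# A toy baseline with arbitrary stratum populations (defaults tiny).
toy_baseline <- function(cats = c(UL = 100, UM = 100, UH = 100, UVH = 100,
                                  RL = 100, RM = 100, RH = 100, RVH = 100)) {
  df <- data.frame(
    scenario = scenario_keys(),
    habitat = ifelse(substr(scenario_keys(), 1, 1) == "U", "urban",
                     "rural"),
    potential = substring(scenario_keys(), 2),
    cats = as.numeric(cats[scenario_keys()]),
    colonies = 0
  )
  class(df) <- c("cat_baseline", "data.frame")
  df
}

# Simulation parameters with all exogenous processes switched off, for
# closed-form checks.
bare_params <- function(baseline, ...) {
  sim_params(baseline, catastrophe = NULL, flows = NULL, capacity = NULL,
             ...)
}
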