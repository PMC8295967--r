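# Shared small fixtures, built once per test run.
england_book <- fixture_parameter_book("england")
flat_book <- fixture_parameter_book("england", scenario = "flat")
default_ext <- generate_external_inputs(seed = 11)
flat_ext <- generate_external_inputs(seed = 11, scenario = "flat")

draw_sample_seeded <- function(book, seed) {
  set.seed(seed)
  draw_sample(book)
}

# Equity settings with round numbers for hand-checkable arithmetic.
toy_equity <- function(epsilon = 1, shares = c(0.3, 0.25, 0.2, 0.15, 0.1),
                       qale = rep(70, 5), pop = rep(1e6, 5), k = 20000) {
  equity_settings(threshold = k, opp_cost_shares = shares, epsilon = epsilon,
                  qale = qale, quintile_pop = pop)
}
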