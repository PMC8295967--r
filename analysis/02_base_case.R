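#!/usr/bin/env Rscript
# Deterministic base case at the parameter means: population iNHB and
# inequality impact (iEDE - iNHB) for every pairwise comparison in all
# three regions.
suppressPackageStartupMessages(library(dceasmoke))

dir.create("results", showWarnings = FALSE)
ext <- generate_external_inputs(seed = 1)

rows <- list()
for (region in c("england", "york", "sheffield")) {
  book <- fixture_parameter_book(region)
  for (r in base_case_results(book, ext)) {
    rows[[length(rows) + 1]] <- data.frame(
      region = region, comparison = r$comparison, inhb = r$inhb,
      inequality_impact = r$delta, quadrant = r$quadrant)
    message(sprintf("%-9s %-28s iNHB %10.0f QALYs, inequality impact %8.0f (%s)",
                    region, r$comparison, r$inhb, r$delta, r$quadrant))
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/base_case.csv", row.names = FALSE)

message("\nBoth active interventions improve overall health in every region but widen")
message("the health gap (win-lose): quitting helps everyone, yet uptake and quit")
message("success are lower in deprived quintiles while opportunity costs fall on them.")
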