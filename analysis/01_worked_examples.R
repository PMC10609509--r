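#!/usr/bin/env Rscript
# Analytic worked examples: how many substitutions each substitution rate
# category (SRC) contributes along a short branch.
#
# A 0.05 substitutions/site branch on a 2596-site alignment carries
# 129.8 expected substitutions. The slowest of 12 equiprobable
# discrete-gamma categories (alpha = 0.803) evolves ~0.023x the mean rate,
# so its 216.3 sites contribute only ~0.25 of those substitutions (0.19%);
# the fastest category (~3.82x) contributes ~41.4 (31.9%). Short branches
# are therefore nearly invisible to slow-evolving sites.

suppressMessages(library(slowfast))
dir.create("results", showWarnings = FALSE)

g <- discretize_gamma(0.803, 12)
write_tsv <- function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE)
write_tsv(data.frame(category = 1:12, rate = signif(g$rates, 5)),
          "results/category_rates.tsv")

branch <- 0.05
rows <- do.call(rbind, lapply(1:12, function(c) {
  e <- expected_substitutions(branch, 2596, 12, g$rates[c])
  data.frame(category = c, rate = signif(g$rates[c], 4),
             expected_count = round(e$count, 2),
             percent_of_branch_total = round(100 * e$fraction, 3))
}))
write_tsv(rows, "results/worked_examples.tsv")

message("branch total: ", 2596 * branch, " substitutions")
message("SRC1 contributes ", rows$expected_count[1], " (",
        rows$percent_of_branch_total[1], "%); SRC12 contributes ",
        rows$expected_count[12], " (", rows$percent_of_branch_total[12], "%)")
message("wrote results/category_rates.tsv, results/worked_examples.tsv")
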