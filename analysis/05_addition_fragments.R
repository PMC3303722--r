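#!/usr/bin/env Rscript
# Tabulate the 3' addition fragments recovered by trim-rescue mapping in
# both simulated libraries and compare them with the generating spectrum.
# Run analysis/02 and 03 first.

suppressPackageStartupMessages(library(isomirarm))

res <- readRDS("results/pipeline_result.rds")
write_addition_tsv(res$additions_a, res$additions_b,
                   "results/sim_addition_fragments.tsv")
for (lib in c("a", "b")) {
  tab <- res[[paste0("additions_", lib)]]
  cat(sprintf("library %s: %d fragment kinds, %s added reads (%.1f%% of mapped)\n",
              toupper(lib), tab$n_kinds,
              format(tab$added_reads, big.mark = ","),
              100 * tab$addition_rate))
}
cat("top fragments in library A:\n")
print(head(transform(res$additions_a$fragments,
                     pct = round_half_up(pct, 2)), 8))
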