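#!/usr/bin/env Rscript
# Materialise the synthetic demo dataset: four seat conditions (SPA 0-15 deg),
# Exp/Sim force tables, pressure grids for both surfaces, and unloaded/loaded
# tissue mesh pairs with and without sliding. Everything downstream
# (02-05) reads from results/fixtures.

library(sitpress)

out <- "results/fixtures"
cfg_path <- write_fixture_set(out, seed = 20260925)
cat("Fixture set written under", out, "\n")
cat("Study config:", cfg_path, "\n")
cat("Files:", length(list.files(out)), "\n")
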