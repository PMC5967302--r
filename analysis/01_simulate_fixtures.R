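#!/usr/bin/env Rscript
# Generate one synthetic dataset of each kind through the config-driven
# pipeline, with manifests and checksums, under results/fixtures/. These are
# the example inputs the later drivers analyze from disk.

library(myoquant)

out <- "results/fixtures"
seed <- 20260926 %% 100000

for (what in c("field", "cortical", "trap", "tether", "fura2",
               "population")) {
  dir <- file.path(out, what)
  m <- run_pipeline(list(task = "simulate", what = what, seed = seed,
                         params = switch(what,
                                         field = list(noise_sd = 2),
                                         cortical = list(noise_sd = 2),
                                         trap = list(stiffness = 7.29),
                                         tether = list(trap_stiffness = 7.29,
                                                       tether_stiffness = 10,
                                                       noise_sd = 0.002),
                                         fura2 = list(noise_sd = 0.01),
                                         list())),
                   dir)
  message(sprintf("%-10s -> %s (%d files)", what, dir, length(m$files)))
}
message("done; manifests record seeds, parameters and md5 checksums")
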