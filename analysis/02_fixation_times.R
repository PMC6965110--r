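#!/usr/bin/env Rscript
# Mean fixation times (given fixation) from the diffusion boundary-value
# solver, with calendar-year conversions at 25 and 30 years per generation.
#
# The question: does a mutation that does fix do so fast enough to fit a
# ~100 000-year window? Near-neutral mutations need ~4N generations; strong
# selection cuts this drastically.

library(fixstep)

outdir <- "results"
N_grid <- c(100, 500, 1500, 5000, 15000)
s_grid <- c(1e-6, 0.01, 0.05, 0.1, 0.5, 1)

tab <- fixation_time_table(N = N_grid, s = s_grid, scheme_type = "dominant",
                           config = time_solver_config(grid_points = 2000))
write_result_table(tab, file.path(outdir, "fixation_times.csv"),
                   metadata = list(N = N_grid, s = s_grid, scheme = "dominant",
                                   grid_points = 2000,
                                   generation_years = c(25, 30)))

message("Mean generations to fixation (dominant scheme, fixed lineages only):")
for (N in N_grid) {
  sub <- tab[tab$N == N, ]
  message(sprintf("  N=%5d: %s", N,
                  paste(sprintf("s=%g: %.0f", sub$s_het, sub$t_conditional),
                        collapse = " | ")))
}

drift <- tab[tab$s_het == 1e-6, ]
message("\nFindings:")
message(sprintf("  * Near-neutral fixation takes ~4N generations (computed/4N: %s),",
                paste(sprintf("%.3f", drift$t_conditional / (4 * drift$N)),
                      collapse = ", ")))
message("    i.e. 100k-1.8M years at N = 1500, 25-30 y/generation.")
strong <- tab[tab$s_het == 1 & tab$N == 1500, ]
message(sprintf("  * A dominant s=1 macro-mutation at N=1500 fixes in ~%.0f generations (%.0f-%.0f years):",
                strong$t_conditional, strong$years_low, strong$years_high))
message("    fixation *time* is no obstacle to either hypothesis; the bottleneck is occurrence.")
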