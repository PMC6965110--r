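#!/usr/bin/env Rscript
# The distribution of beneficial-effect sizes and its estimation.
#
# Extreme value theory predicts exponential effect sizes for beneficial
# mutations in a well-adapted genome. Empirical estimates of E[Delta1] (the
# expected gap between the best and second-best mutant) come from viral
# fitness assays and fall between ~1/53 (MLE) and ~1/37 (least squares);
# 1/30 is used downstream as a deliberately generous value for large
# mutations. Here we generate a synthetic data set with that structure
# ("random" effects = as they occur; "preobserved" = occurred and fixed),
# fit it both ways, and overlay the predicted fixation-filtered curve.

library(fixstep)

outdir <- "results"
seed <- 20260920
n_random <- 200
n_preobserved <- 200

spec <- synthetic_spec(e_delta1 = 1 / 30, n_random = n_random,
                       n_preobserved = n_preobserved, N = Inf, seed = seed)
random_sample <- generate_random_effects(spec)
pre_sample <- generate_preobserved_effects(spec)
write_effects_table(random_sample, file.path(outdir, "synthetic_random_effects.csv"))
write_effects_table(pre_sample, file.path(outdir, "synthetic_preobserved_effects.csv"))

rep <- fit_effects_report(random_sample, N = Inf)
write_result_table(rep$predicted, file.path(outdir, "effect_fit_curves.csv"),
                   metadata = list(seed = seed, n_random = n_random,
                                   e_delta1_true = 1 / 30,
                                   e_delta1_mle = rep$mle$e_delta1,
                                   e_delta1_lsq = rep$lsq$e_delta1,
                                   N_mode = "Inf (finite-size term dropped)"))

message(sprintf("True E[Delta1] = 1/30 = %.5f. Fits on %d synthetic 'random' effects:",
                1 / 30, n_random))
message(sprintf("  maximum likelihood: E[Delta1] = %.5f (1/%.1f), SE %.5f",
                rep$mle$e_delta1, 1 / rep$mle$e_delta1, attr(rep$mle, "se")))
message(sprintf("  least squares (bin frequencies): E[Delta1] = %.5f (1/%.1f)",
                rep$lsq$e_delta1, 1 / rep$lsq$e_delta1))

ks <- suppressWarnings(ks.test(pre_sample$effects, function(s)
  improvement_cdf(s, rep$improvement))$statistic)
message(sprintf("  predicted fixation-filtered CDF vs %d 'preobserved' draws: KS distance %.3f",
                n_preobserved, ks))
message("\nFindings:")
message("  * Both estimators recover the exponential scale from occurrence data alone.")
message(sprintf("  * Fixation filtering shifts the mean effect from %.4f (random) to %.4f (preobserved):",
                mean(random_sample$effects), mean(pre_sample$effects)))
message("    what we observe after evolution over-represents large-effect mutations.")
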