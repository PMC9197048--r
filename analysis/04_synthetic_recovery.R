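#!/usr/bin/env Rscript

# End-to-end recovery study on seeded synthetic sessions: 50 sessions
# (5 annulus-width conditions x 20 trials, 8 units each) are pushed
# through the full LFP + spiking pipeline.  Reports the per-site
# normalized-gamma and firing-rate regression slopes, the paired
# signed-rank comparison of their magnitudes, and the recovered
# attenuation constant.  A model-driven variant maps the discontinuity
# onto wee reduction instead of a programmed amplitude law.

library(gammaEI)
dir.create("results", showWarnings = FALSE)

n_sessions <- 50
rows <- vector("list", n_sessions)
for (s in seq_len(n_sessions)) {
  an <- analyze_session(generate_session(session_config(seed = s)))
  pc <- an$per_condition
  rows[[s]] <- data.frame(
    seed = s, gamma_slope = an$gamma_slope, rate_slope = an$rate_slope,
    lambda_hat = tryCatch(
      recover_attenuation(pc$delta_band_power, pc$magnitude),
      error = function(e) NA_real_))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/session_slopes.csv", row.names = FALSE)

wsr <- paired_comparison(abs(tab$gamma_slope), abs(tab$rate_slope))
cat(sprintf("gamma slope negative in %d / %d sessions (median %.3f /deg)\n",
            sum(tab$gamma_slope < 0), n_sessions,
            median(tab$gamma_slope)))
cat(sprintf("rate slope median %.3f /deg\n", median(tab$rate_slope)))
cat(sprintf("|gamma slope| > |rate slope|: signed-rank z = %.2f, p = %.3g (n = %d)\n",
            wsr$statistic, wsr$p_value, wsr$n))
cat(sprintf("attenuation constant: programmed 0.1 deg, recovered median %.4f deg\n",
            median(tab$lambda_hat, na.rm = TRUE)))

md <- generate_model_driven_session(
  ei_model_spec(), c(1, 0.9, 0.8),
  session_config(discontinuity_levels = c(0, 0.1, 0.2), seed = 1))
an_md <- analyze_session(md)
write.csv(an_md$per_condition, "results/model_driven_session.csv",
          row.names = FALSE)
cat("\nmodel-driven session (discontinuity -> wee scale 1 / 0.9 / 0.8):\n")
print(an_md)
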