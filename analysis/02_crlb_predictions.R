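#!/usr/bin/env Rscript
# Cramer-Rao precision predictions for both readouts.
#
# The simulation noise level is anchored once: sigma is calibrated so the
# monopolar reference protocol (32 echoes, 97 ms range, alpha 75 deg,
# TR 1200 ms, T2* 69 ms tissue) has a predicted T2* standard deviation of
# 1.08 ms. Every other protocol cell is then predicted with that same
# sigma, which makes the table a pure statement about sampling geometry
# and SNR scaling.

library(met2star)
dir.create("results", showWarnings = FALSE)

tis <- tissue_params(m0 = 1, t1 = 878, t2_star = 69)
mono <- train_from_protocol(3.84, 2.92, "monopolar", te_max = 97)
bip <- train_from_protocol(3.84, 1.47, "bipolar", te_max = 97)

sigma0 <- calibrate_sigma(1.08, mono, tis, acquisition_params(75, 1200))
message(sprintf("Calibrated sigma0 = %.6g (anchor: monopolar 75deg -> 1.08 ms)",
                sigma0))

rows <- list()
for (alpha in c(15, 35, 75)) for (r in c(26, 52, 97))
  for (scheme in c("monopolar", "bipolar")) {
    dte <- if (scheme == "monopolar") 2.92 else 1.47
    train <- train_from_protocol(3.84, dte, scheme, te_max = r)
    std <- crlb_t2star_std(train, tis, acquisition_params(alpha, 1200),
                           sigma = sigma0)
    rows[[length(rows) + 1L]] <- data.frame(
      alpha = alpha, te_range = r, scheme = scheme, n_e = train$n_e,
      crlb_std = std)
  }
tab <- do.call(rbind, rows)
write.csv(tab, "results/crlb_predictions.csv", row.names = FALSE)

full <- tab[tab$te_range == 97, ]
message("Full-range CRLB std (ms) by flip angle:")
for (a in unique(full$alpha)) {
  m <- full$crlb_std[full$alpha == a & full$scheme == "monopolar"]
  b <- full$crlb_std[full$alpha == a & full$scheme == "bipolar"]
  message(sprintf("  alpha %2d: mono %.3f, bipolar %.3f (ratio %.3f, sqrt(2) = %.3f)",
                  a, m, b, m / b, sqrt(2)))
}
message("Doubling the echo density halves the variance: the bipolar bound sits ",
        "a factor ~sqrt(2) below the monopolar one in every cell.")
message("Wrote results/crlb_predictions.csv")
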