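# Published multi-echo GRE acquisition protocols, keyed by receiver
# bandwidth per pixel. te1/delta_te are the printed values; te_max is the
# maximum TE range achievable at TR = 1200 ms.
protocols:
  bw801:
    bw_per_px_hz: 801
    matrix: 240
    n_x: 240
    te1_ms: 3.84
    delta_te_mono_ms: 2.92
    delta_te_bip_ms: 1.47
    te_max_ms: 97
  bw718:
    bw_per_px_hz: 718
    matrix: 240
    n_x: 240
    te1_ms: 3.90
    delta_te_mono_ms: 3.05
    delta_te_bip_ms: 1.60
    te_max_ms: 97
  bw613:
    bw_per_px_hz: 613
    matrix: 240
    n_x: 240
    te1_ms: 4.00
    delta_te_mono_ms: 3.27
    delta_te_bip_ms: 1.82
    te_max_ms: 97
  bw342:
    bw_per_px_hz: 342
    matrix: 240
    n_x: 240
    te1_ms: 4.62
    delta_te_mono_ms: 4.48
    delta_te_bip_ms: 3.03
    te_max_ms: 97
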