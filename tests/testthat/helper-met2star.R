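# Shared fixtures, built in code. The reference protocol is the
# 801 Hz/px acquisition: TE1 = 3.84 ms, echo spacing 2.92 ms (monopolar)
# and 1.47 ms (bipolar).

mono97 <- function() train_from_protocol(3.84, 2.92, "monopolar", te_max = 97)
bip97 <- function() train_from_protocol(3.84, 1.47, "bipolar", te_max = 97)

roi3_tissue <- function() tissue_params(m0 = 1, t1 = 878, t2_star = 69)

# Cached small phantom for structural tests.
.fixture_env <- new.env()
small_phantom <- function() {
  if (is.null(.fixture_env$ph)) .fixture_env$ph <- build_default_phantom(96)
  .fixture_env$ph
}
full_phantom <- function() {
  if (is.null(.fixture_env$ph240)) .fixture_env$ph240 <- build_default_phantom(240)
  .fixture_env$ph240
}
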