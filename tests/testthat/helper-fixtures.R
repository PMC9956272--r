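# Shared fixtures, built once per test run.  Everything is generated in
# code under fixed seeds; nothing is read from disk.

TPL <- tcme_templates(seed = 7)
REF <- tcme_reference(TPL)
SEED_PROTEINS <- synthetic_ruvc_seed(n = 24, seed = 11)
PROF <- build_ruvc_profile(SEED_PROTEINS)

# a comfortably separating scan threshold: far above decoy noise (~25 bits
# at the 99.9th percentile on shuffles), far below genuine domain scores
# (>300 bits); the calibration itself is tested separately
THR <- 40
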