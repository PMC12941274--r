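# Shared settings for the analysis scripts: one master seed, one report
# directory. Every script can be run standalone; later scripts regenerate
# what they need from the same seed, so results are consistent across the
# sequence.
library(zfam)

MASTER_SEED <- 20260927L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
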