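# Shared configuration for the analysis drivers. Each numbered script is a
# resumable stage: it reads what earlier stages wrote under results/ and
# writes its own tables there, so the stages can be re-run individually.

library(mirmint)

SEED <- 20260930
RESULTS <- "results"
INPUTS <- file.path(RESULTS, "inputs")
dir.create(INPUTS, recursive = TRUE, showWarnings = FALSE)

STUDY_CFG <- study_config(n_genes = 2000, n_mirnas = 100,
                          n_planted_regulators = 5,
                          repression_strength = -1, noise_sd = 0.1,
                          seed = SEED)
PIPE_CFG <- pipeline_config(n_rep = 500, n_perm = 999, seed = SEED)

msg <- function(...) cat(sprintf(...), "\n")
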