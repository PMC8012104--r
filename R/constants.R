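# Canonical predictor names, shared across modules.
.sim_names <- c("word_sent", "sent_sent", "sent_para", "para_para")
.covariate_names <- c("freq", "surprisal", .sim_names)
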