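# non-standard-evaluation column names used inside ggplot2 aes()
utils::globalVariables(c("bp", "reference", "sample", "probe_id", "dq",
                         "gene"))
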