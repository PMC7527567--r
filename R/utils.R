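`%||%` <- function(a, b) if (is.null(a)) b else a

# one-decimal formatting used by the human-readable report
fmt1 <- function(x) formatC(x, format = "f", digits = 1)
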