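`%||%` <- function(a, b) if (is.null(a)) b else a

# consistent edge key for named lists indexed by node pairs
edge_key <- function(s, t) paste(sort(c(s, t)), collapse = "|")

# population variance (divides by n); for a 0/1 vector this equals p(1-p)
pop_var <- function(x) mean((x - mean(x))^2)

stop_input <- function(...) stop(..., call. = FALSE)
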