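# Classed condition for parameter combinations that imply a probability
# outside [0, 1]; the PSA catches these to resample a draw.
stop_infeasible <- function(...) {
  stop(structure(class = c("strokepgx_infeasible", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
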