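# Classed conditions so callers (and the command-line wrapper) can map
# failure modes to distinct exit codes.

ps_stop <- function(class, msg, ...) {
  msg <- sprintf(msg, ...)
  stop(structure(
    class = c(class, "pseudoscan_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_io      <- function(msg, ...) ps_stop("ps_io_error", msg, ...)
stop_format  <- function(msg, ...) ps_stop("ps_format_error", msg, ...)
stop_model   <- function(msg, ...) ps_stop("ps_model_error", msg, ...)
stop_label   <- function(msg, ...) ps_stop("ps_label_error", msg, ...)
stop_config  <- function(msg, ...) ps_stop("ps_config_error", msg, ...)
stop_tree    <- function(msg, ...) ps_stop("ps_tree_error", msg, ...)
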