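# Structured error conditions. The CLI maps schema/config errors to exit
# code 2 and everything else to 3, so every user-facing failure funnels
# through one of these constructors.

msi_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "msiclass_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

stop_schema <- function(msg) msi_stop(msg, "msiclass_schema_error")
stop_parse  <- function(msg) msi_stop(msg, c("msiclass_parse_error", "msiclass_schema_error"))
stop_config <- function(msg) msi_stop(msg, "msiclass_config_error")
stop_state  <- function(msg) msi_stop(msg, "msiclass_state_error")
stop_key    <- function(msg) msi_stop(msg, "msiclass_key_error")
stop_data   <- function(msg) msi_stop(msg, "msiclass_data_error")
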