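# internal numeric helpers ---------------------------------------------------

LN10 <- log(10)

#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# thermal voltage kT/e in volts at temperature T (kelvin)
thermal_voltage <- function(temperature) {
  stopifnot(temperature > 0)
  8.617333262e-5 * temperature
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# numeric-or-NA coercion for sparse CSV cells
num_or_na <- function(x) {
  x <- as.character(x)
  x[!nzchar(trimws(x))] <- NA_character_
  suppressWarnings(as.numeric(x))
}

chr_or_na <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA_character_
  x
}

abort_kc <- function(msg, class) {
  stop(structure(class = c(class, "kinconsist_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

format_error <- function(msg) abort_kc(msg, "kinconsist_format_error")
validation_error <- function(msg) abort_kc(msg, "kinconsist_validation_error")
numeric_error <- function(msg) abort_kc(msg, "kinconsist_numeric_error")
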