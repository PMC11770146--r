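# Internal helpers: argument checking and engineering-notation formatting.

#' Vacuum permittivity (F/m)
#'
#' The electric constant used throughout the package.
#' @export
EPS0 <- 8.8541878128e-12

stop_invalid <- function(...) {
  stop(structure(class = c("depspin_invalid", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_domain <- function(...) {
  stop(structure(class = c("depspin_domain", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a single finite number")
  if (strict_min && x <= min)
    stop_invalid(name, " must be > ", min, " (got ", x, ")")
  if (!strict_min && x < min)
    stop_invalid(name, " must be >= ", min, " (got ", x, ")")
  if (strict_max && x >= max)
    stop_invalid(name, " must be < ", max, " (got ", x, ")")
  if (!strict_max && x > max)
    stop_invalid(name, " must be <= ", max, " (got ", x, ")")
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stop_invalid(name, " must be a whole number")
  if (x < min) stop_invalid(name, " must be >= ", min)
  as.integer(x)
}

# Engineering-prefix pretty printer: si_format(3.5e6, "Hz") -> "3.5 MHz"
si_format <- function(x, unit = "", digits = 3) {
  if (!is.finite(x)) return(paste(x, unit))
  if (x == 0) return(paste(0, unit))
  prefixes <- c("y" = -24, "z" = -21, "a" = -18, "f" = -15, "p" = -12,
                "n" = -9, "µ" = -6, "m" = -3, " " = 0, "k" = 3,
                "M" = 6, "G" = 9, "T" = 12)
  e3 <- 3 * floor(log10(abs(x)) / 3)
  e3 <- max(min(e3, 12), -24)
  p <- names(prefixes)[match(e3, prefixes)]
  val <- signif(x / 10^e3, digits)
  trimws(paste0(format(val), " ", sub("^ $", "", p), unit))
}
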