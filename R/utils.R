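#' Round half away from zero
#'
#' Rounding used for all printed-style renderings (percentages, implied
#' counts). R's `round()` rounds half to even; clinical tables round
#' half up, so 45.83 -> 46 and 11.99 -> 12 (and 0.5 -> 1, not 0).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.5)        # 1
#' round_half_up(45.83, 0)   # 46
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Render a proportion as a percentage string
#'
#' Central rendering rule: proportions are shown as percentages rounded
#' half up. One decimal is the convention of diagnostic-accuracy tables
#' (e.g. "36.4%"); integer rendering is used for prevalence ("46%").
#'
#' @param p proportion in \[0, 1\].
#' @param digits decimal places (default 1).
#' @param symbol append a percent sign (default TRUE).
#' @return character vector.
#' @export
render_percent <- function(p, digits = 1, symbol = TRUE) {
  val <- round_half_up(100 * p, digits)
  out <- formatC(val, format = "f", digits = digits)
  if (symbol) paste0(out, "%") else out
}

#' Render a ratio (e.g. a likelihood ratio) to fixed decimals, half up
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return character vector.
#' @export
render_ratio <- function(x, digits = 1) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

# internal: stop with a classed condition so callers can test error classes
th2_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "th2_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# internal: scalar checks
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_scalar_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# internal: run code with a seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
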