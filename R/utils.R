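# Internal helpers shared across modules.

#' Round half away from zero
#'
#' IEEE `round()` rounds half to even; report tables use conventional
#' half-up rounding (2.345 -> 2.35 at 2 digits).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Signal a classed error so pipeline stages can be identified downstream.
stop_treedraw <- function(msg, class, stage = NULL, call. = FALSE) {
  cond <- structure(
    class = c(class, "treedraw_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1), stage = stage)
  )
  stop(cond)
}

# Re-signal any error from `expr` with the pipeline stage name attached.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    msg <- sprintf("stage %s: %s", stage, conditionMessage(e))
    cls <- setdiff(class(e), c("error", "condition"))
    cond <- structure(
      class = unique(c(cls, "treedraw_stage_error", "error", "condition")),
      list(message = msg, call = NULL, stage = stage)
    )
    stop(cond)
  })
}

# Bounding box of a logical matrix: (top, bottom, left, right), 1-based.
mask_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (length(rows) == 0) return(NULL)
  c(top = rows[1], bottom = rows[length(rows)],
    left = cols[1], right = cols[length(cols)])
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x)
}
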