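# Internal helpers: argument validation and physical constants.

# atomic masses, g/mol
M_P  <- 30.974
M_FE <- 55.845

# yield of metamorphic P(V) -> P(III) reduction at 350 degC (fraction),
# from hydrothermal experiments on ferruginous sediments
METAMORPHIC_YIELD_350C <- 0.00075

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%g, %g] (got %g)", name, lower, upper, x),
         call. = FALSE)
  invisible(x)
}

.assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min)
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

.assert_numeric_vec <- function(x, name, lower = -Inf, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be a finite numeric vector of length >= %d",
                 name, min_len), call. = FALSE)
  if (any(x < lower))
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  invisible(x)
}

.assert_range <- function(x, name, lower = 0, upper = Inf) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x))
    stop(sprintf("'%s' must be a numeric vector c(min, max)", name),
         call. = FALSE)
  if (x[1] > x[2])
    stop(sprintf("'%s' must satisfy min <= max", name), call. = FALSE)
  if (x[1] < lower || x[2] > upper)
    stop(sprintf("'%s' must lie within [%g, %g]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

.assert_cols <- function(df, cols, name) {
  if (!is.data.frame(df))
    stop(sprintf("'%s' must be a data.frame", name), call. = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("'%s' is missing column(s): %s", name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}
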