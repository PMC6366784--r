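# Small shared helpers: ordinal levels, rounding conventions, seeded-stream scoping.

#' Ordinal qualitative levels used throughout the assessment
#'
#' Risk categories and uncertainty grades share the ordering
#' low < moderate < high.
#' @keywords internal
.levels3 <- c("low", "moderate", "high")

#' @keywords internal
as_level3 <- function(x, what = "level") {
  x <- as.character(x)
  bad <- !(x %in% .levels3) & !is.na(x)
  if (any(bad)) {
    stop(sprintf("invalid %s: %s (must be one of %s)", what,
                 paste(unique(x[bad]), collapse = ", "),
                 paste(.levels3, collapse = ", ")), call. = FALSE)
  }
  factor(x, levels = .levels3, ordered = TRUE)
}

#' Round half away from zero
#'
#' Tabular output convention: one decimal, halves rounded away from zero
#' (so 1688.55 prints as 1688.6). Base `round()` rounds halves to even,
#' which does not reproduce printed summary tables.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Population standard deviation (n denominator)
#'
#' @param x numeric vector.
#' @return sqrt(mean((x - mean(x))^2)); 0 for length-1 input, NA for empty.
#' @export
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
# Each synthetic-data component draws from its own stream so that, e.g.,
# changing the number of ports does not perturb the fleet draws.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stable stable aggregation helper: aggregate a numeric column by key columns
# keeping keys as character/integer, rows ordered by key.
agg_by <- function(df, value_col, key_cols, fun) {
  if (nrow(df) == 0L) {
    out <- df[, key_cols, drop = FALSE]
    out$value <- numeric(0)
    return(out)
  }
  key <- interaction(df[key_cols], drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(df)), key)
  out <- df[vapply(idx, `[`, 1L, FUN.VALUE = integer(1)), key_cols, drop = FALSE]
  out$value <- vapply(idx, function(i) fun(df[[value_col]][i]), numeric(1))
  rownames(out) <- NULL
  out
}
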