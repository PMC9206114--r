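#' Round half away from zero
#'
#' Base [round()] rounds half to even; reported cohort percentages follow
#' the usual half-up convention (e.g. 12/112 -> 10.7%).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up at `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(0.125, 10.714), 2)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a stage-specific random seed
#'
#' Every stage that consumes randomness derives its own seed from the single
#' run seed and a stage label, so adding a stage never shifts the random
#' stream of another stage.
#'
#' @param seed integer run seed.
#' @param stage character stage label.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # small rolling-polynomial hash of the label, folded with the run seed
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147480009
  as.integer((abs(seed) %% 2147480009 * 7919 + h) %% 2147480009)
}

variant_id <- function(chromosome, position, ref, alt) {
  paste(chromosome, position, ref, alt, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
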