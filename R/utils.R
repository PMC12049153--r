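`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a stage-specific seed from a global seed
#'
#' Stochastic stages of the pipeline draw their own seeds from the global
#' seed and the stage name, so that toggling one stage never perturbs the
#' random stream of another. The derivation is a fixed integer hash kept
#' below 2^31.
#'
#' @param seed Integer global seed.
#' @param stage Character scalar naming the stage (e.g. `"nmf"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(as.double(utf8ToInt(stage)) * (31 ^ (seq_along(utf8ToInt(stage)) %% 7)))
  as.integer((abs(as.double(seed)) * 48271 + h * 2654435.0) %% 2147483645) + 1L
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a scalar in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

#' @noRd
pearson_dist <- function(mat) {
  r <- stats::cor(t(as.matrix(mat)))
  r[!is.finite(r)] <- 0
  stats::as.dist(1 - r)
}
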