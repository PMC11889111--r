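# Internal utilities.

#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      suppressWarnings(rm(".Random.seed", envir = env))
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed, kept inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483587 * 48271 + as.double(i) * 10007) %% 2147483587)
}

# Degrees of head rotation spanning one normalized scene unit; nominal value
# for an 82-degree horizontal field-of-view scene camera, used both by the
# generator's head-gaze coupling and by saccade compensation.
DEG_PER_SCENE_UNIT <- 82

wrap_angle_deg <- function(x) {
  ((x + 180) %% 360) - 180
}

# Sample-variance with a 0 fallback for length-1 input.
var0 <- function(x) if (length(x) < 2L) 0 else stats::var(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
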