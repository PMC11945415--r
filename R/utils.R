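# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Signal a classed error so callers can discriminate failure modes.
# type is one of: validation, degenerate, fit_failure, segmentation,
# ambiguous_orientation, insufficient_section, spec.
hc_stop <- function(msg, type = "validation", call. = FALSE) {
  cls <- c(paste0("hc_error_", type), "hc_error", "error", "condition")
  stop(structure(class = cls, list(message = msg, call = NULL)))
}

# Evaluate expr under a private RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. seed = NULL runs expr with the current state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    hc_stop("seed must be a single finite number")
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Coerce an hc_points object or a plain n x 3 matrix to the bare coordinate
# matrix used by the geometry code.
as_xyz <- function(points) {
  if (inherits(points, "hc_points")) return(points$xyz)
  m <- as.matrix(points)
  if (ncol(m) != 3L) hc_stop("points must be an hc_points object or an n x 3 matrix")
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- c("x", "y", "z")
  m
}

vnorm <- function(v) sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# mm -> cm at API boundaries; all internal geometry is millimetres.
mm_to_cm <- function(x) x / 10
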