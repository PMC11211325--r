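# Structured error conditions. Every user-facing validation failure carries a
# distinct condition class "fcsubtype_<what>" so callers (and tests) can
# discriminate failure modes without parsing messages.

fcStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c(paste0("fcsubtype_", class),
                                     "fcsubtype_error")))
}

assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    fcStop("bad_argument", "'%s' must be a single finite number", name)
  invisible(x)
}

assertSquareSymmetric <- function(m, tol = 1e-12, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    fcStop("not_square", "'%s' must be a square matrix", name)
  if (max(abs(m - t(m))) > tol)
    fcStop("not_symmetric", "'%s' is not symmetric within %g", name, tol)
  invisible(m)
}
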