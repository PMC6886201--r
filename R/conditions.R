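# Typed conditions so callers (and the CLI) can map failures to exit codes.

jde_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "jde_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

jde_stop_usage      <- function(msg) jde_stop(msg, "jde_usage_error")
jde_stop_validation <- function(msg) jde_stop(msg, "jde_validation_error")
jde_stop_numeric    <- function(msg) jde_stop(msg, "jde_numeric_error")

# Single QR-based solver seam: rank deficiency surfaces as a typed error,
# never as a noisy near-singular solve.
solve_qr <- function(A, b) {
  qa <- qr(A)
  if (qa$rank < ncol(A)) {
    jde_stop_numeric("rank-deficient linear system: covariates unidentifiable after centering")
  }
  qr.coef(qa, b)
}

# (X'X)^{-1} for a centered design, via the same seam.
xtx_inverse <- function(x_tilde) {
  p <- ncol(x_tilde)
  solve_qr(crossprod(x_tilde), diag(p))
}
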