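#' Linear ballistic accumulator parameter set
#'
#' Bundles one parameterization of the LBA race. Each response option `i`
#' accrues evidence linearly from a starting point drawn uniformly on
#' `[0, A]` at a rate drawn once per trial from `N(v[i], s)`, until the
#' first accumulator reaches the threshold `b = k + A`. The observed
#' response time adds a nondecision component `t0`. Response caution is
#' the derived quantity `b - A/2`: the average evidence that must be
#' accrued before a response.
#'
#' @param v numeric vector of mean drift rates, one per response option
#'   (at least two options).
#' @param A maximum starting evidence (upper bound of the uniform start
#'   point), `A >= 0`.
#' @param k relative threshold, the gap between the maximal start point
#'   and the response threshold, `k > 0`. The threshold is `b = k + A`.
#' @param t0 nondecision time in seconds, `t0 >= 0`.
#' @param s between-trial drift standard deviation, fixed at 1 as the
#'   model's scaling constant unless overridden.
#'
#' @return An object of class `lba_params`: a list with elements `v`,
#'   `s`, `A`, `k`, `b`, `t0` and `caution`.
#' @examples
#' p <- lba_params(v = c(2, 1), A = 0.5, k = 0.5, t0 = 0.15)
#' p$b        # 1.0
#' p$caution  # 0.75
#' @export
lba_params <- function(v, A, k, t0, s = 1) {
  stopifnot(is.numeric(v), length(v) >= 2, all(is.finite(v)))
  stopifnot(length(A) == 1, is.finite(A), A >= 0)
  stopifnot(length(k) == 1, is.finite(k), k > 0)
  stopifnot(length(t0) == 1, is.finite(t0), t0 >= 0)
  stopifnot(length(s) == 1, is.finite(s), s > 0)
  structure(
    list(v = as.numeric(v), s = as.numeric(s), A = as.numeric(A),
         k = as.numeric(k), b = as.numeric(k + A), t0 = as.numeric(t0),
         caution = as.numeric(k + A - A / 2)),
    class = "lba_params")
}

#' @export
print.lba_params <- function(x, ...) {
  cat("LBA parameters (", length(x$v), " response options)\n", sep = "")
  cat("  v  =", paste(signif(x$v, 4), collapse = ", "), "\n")
  cat("  s  =", signif(x$s, 4), " A =", signif(x$A, 4),
      " k =", signif(x$k, 4), " b =", signif(x$b, 4),
      " t0 =", signif(x$t0, 4), "\n")
  cat("  caution (b - A/2) =", signif(x$caution, 4), "\n")
  invisible(x)
}

#' Response caution of an LBA parameter set
#'
#' Caution is `b - A/2`, the threshold minus the mean starting evidence:
#' the average quantity of evidence a response requires. It increases
#' with the relative threshold `k` at fixed `A`, and equals `b` in the
#' point-start limit `A = 0`.
#'
#' @param params an [lba_params] object.
#' @return numeric scalar, evidence units.
#' @export
lba_caution <- function(params) {
  stopifnot(inherits(params, "lba_params"))
  params$b - params$A / 2
}
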