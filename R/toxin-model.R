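# Closed-form toxin-response mathematics: the integrity equation, the
# phenotypic-resistance hit count, dose application and resistance costs.

.checkToxinVectors <- function(a, x = NULL, d = NULL, B = NULL) {
  n <- length(a)
  if (!is.numeric(a) || any(!is.finite(a)))
    stop("sensitivities 'a' must be finite numerics", call. = FALSE)
  if (any(a < 0) || any(a > 1))
    stop("sensitivities 'a' must lie in [0, 1]", call. = FALSE)
  if (!is.null(x)) {
    if (length(x) != n)
      stop("toxin amounts 'x' must match the length of 'a'", call. = FALSE)
    if (any(!is.finite(x)) || any(x < 0))
      stop("toxin amounts 'x' must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(d)) {
    if (length(d) != n)
      stop("doses 'd' must match the length of 'a'", call. = FALSE)
    if (any(!is.finite(d)) || any(d < 0))
      stop("doses 'd' must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(B)) {
    if (!is.matrix(B) || any(dim(B) != n) || any(!is.finite(B)))
      stop("'B' must be a finite ", n, "x", n, " matrix", call. = FALSE)
  }
  invisible(n)
}

.zeroB <- function(n) matrix(0, n, n)

#' Scaled cell integrity given accumulated toxin
#'
#' The integrity of a cell that has accumulated toxin amounts \code{x} is
#' \deqn{I = 1 - \sum_i a_i x_i - \sum_i \sum_j B_{ij} x_i x_j,}
#' a linear damage term weighted by the per-toxin sensitivities plus a full
#' double sum over ordered toxin pairs capturing synergy (\eqn{B_{ij} > 0}),
#' antagonism (\eqn{B_{ij} < 0}) and nonlinear single-toxin dose responses
#' (\eqn{B_{ii} \neq 0}). A symmetric off-diagonal pair therefore contributes
#' twice. Cells die when integrity reaches zero.
#'
#' @param a numeric sensitivities in [0, 1].
#' @param x numeric cumulative toxin amounts, >= 0.
#' @param B toxin interaction matrix; \code{NULL} means purely additive.
#' @return scalar integrity (1 when \code{x} is all zero; can be negative).
#' @examples
#' integrityValue(a = 1, x = 1)                       # 0: one lethal unit
#' integrityValue(a = 0.7, x = 1)                     # 0.3
#' B <- matrix(c(0, 0.05, 0.05, 0), 2, 2)
#' integrityValue(c(0.3, 0.3), c(1, 1), B)            # 1 - 0.6 - 0.1 = 0.3
#' @export
integrityValue <- function(a, x, B = NULL) {
  .checkToxinVectors(a, x = x, B = B)
  I <- 1 - sum(a * x)
  if (!is.null(B)) I <- I - drop(crossprod(x, B %*% x))
  I
}

#' Phenotypic resistance: hits sustainable before death
#'
#' Against an attacker translocating doses \code{d} per hit, a target with
#' sensitivities \code{a} dies after
#' \deqn{N_{hits} = \lceil (\sum_i a_i d_i)^{-1} \rceil}
#' translocation events, i.e. the smallest integer \eqn{n} with
#' \eqn{n \sum_i a_i d_i \ge 1}; a fully insensitive combination
#' (\eqn{\sum a_i d_i = 0}) gives \code{Inf}. The formula assumes purely
#' additive toxins; with a non-zero interaction matrix use
#' \code{\link{hitsToDeath}} instead.
#'
#' @param a numeric sensitivities in [0, 1].
#' @param d numeric doses per hit, >= 0.
#' @return positive integer (as numeric) or \code{Inf}.
#' @examples
#' nHits(1, 1)            # 1: fully sensitive, single lethal hit
#' nHits(0.7, 1)          # 2
#' nHits(c(1, 1), c(1, 1))  # 1
#' nHits(c(0, 0), c(1, 1))  # Inf: immune target
#' @export
nHits <- function(a, d) {
  .checkToxinVectors(a, d = d)
  s <- sum(a * d)
  if (s == 0) return(Inf)
  n <- ceiling(1 / s)
  # pin to the exact death rule n*s >= 1 against floating-point slop
  while (n > 1 && (n - 1) * s >= 1) n <- n - 1
  while (n * s < 1) n <- n + 1
  n
}

#' Apply one translocated dose to a cell
#'
#' Increments the cumulative toxin amounts by \code{d}, recomputes integrity
#' via \code{\link{integrityValue}}, and marks the cell dead once integrity
#' reaches zero. Death is sticky: toxin still accumulates in a corpse
#' (harmless book-keeping) but the flag never reverts.
#'
#' @param state an \code{\linkS4class{IntegrityState}}.
#' @param a numeric sensitivities of the target.
#' @param d numeric doses delivered by this hit.
#' @param B optional toxin interaction matrix.
#' @return the updated \code{IntegrityState}.
#' @examples
#' st <- newIntegrityState(1)
#' st <- applyDose(st, a = 0.7, d = 1)  # I = 0.3, alive
#' st <- applyDose(st, a = 0.7, d = 1)  # dead after the second hit
#' @export
applyDose <- function(state, a, d, B = NULL) {
  stopifnot(is(state, "IntegrityState"))
  .checkToxinVectors(a, x = state@x, d = d, B = B)
  x <- state@x + d
  I <- integrityValue(a, x, B)
  new("IntegrityState", x = x, I = I, dead = state@dead || I <= 0)
}

#' Hits to death by direct simulation of repeated doses
#'
#' Applies \code{\link{applyDose}} until the cell dies and returns the number
#' of applications. Unlike \code{\link{nHits}} this is valid for any
#' interaction matrix \code{B}; with \code{B = NULL} the two agree.
#'
#' After \eqn{n} identical hits the cumulative load is exactly \eqn{n d},
#' so the integrity sequence \eqn{I_n = 1 - n \sum a_i d_i - n^2 d^T B d}
#' is evaluated for \eqn{n = 1, \dots, maxHits} and the first non-positive
#' entry returned (equivalent to, but much faster than, an explicit
#' \code{applyDose} loop).
#'
#' @inheritParams applyDose
#' @param maxHits cap beyond which the target is reported unkillable
#'   (\code{Inf}); strong antagonism can make integrity non-decreasing in
#'   dose, in which case no finite number of hits kills.
#' @return positive integer (as numeric) or \code{Inf}.
#' @export
hitsToDeath <- function(a, d, B = NULL, maxHits = 10000L) {
  .checkToxinVectors(a, d = d, B = B)
  n <- seq_len(maxHits)
  s <- sum(a * d)
  q <- if (is.null(B)) 0 else drop(crossprod(d, B %*% d))
  dead <- which(1 - n * s - n^2 * q <= 0)
  if (!length(dead)) Inf else as.numeric(dead[1])
}

#' Growth-rate multiplier for costly resistance
#'
#' Resistance may carry a fitness penalty proportional to total toxin
#' insensitivity: the specific growth rate is multiplied by
#' \deqn{\max(0,\; 1 - c \sum_i (1 - a_i)),}
#' where \eqn{c} is the cost coefficient. \code{c = 0} (the default
#' throughout) makes resistance free.
#'
#' @param a numeric sensitivities in [0, 1].
#' @param costCoefficient non-negative cost per unit insensitivity.
#' @return multiplier in [0, 1].
#' @examples
#' growthMultiplier(c(0.5, 1), 0.1)  # 0.95
#' @export
growthMultiplier <- function(a, costCoefficient) {
  .checkToxinVectors(a)
  if (!is.numeric(costCoefficient) || length(costCoefficient) != 1L ||
      costCoefficient < 0)
    stop("'costCoefficient' must be a single non-negative number",
         call. = FALSE)
  max(0, 1 - costCoefficient * sum(1 - a))
}
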