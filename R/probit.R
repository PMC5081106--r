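#' Probit and inverse-probit transforms
#'
#' `probit()` maps a proportion to the real line through the standard-normal
#' quantile function; `invProbit()` maps back. These are the link functions
#' used throughout: survey prevalences are modelled, cross-walked and
#' projected on the probit scale.
#'
#' @param p proportion(s) in \[0, 1\].
#' @param q real value(s).
#' @return Numeric vector.
#' @export
probit <- function(p) stats::qnorm(p)

#' @rdname probit
#' @export
invProbit <- function(q) stats::pnorm(q)

#' Continuity-corrected prevalence
#'
#' Observed prevalences of exactly 0 or 1 have infinite probit. Before any
#' probit transformation, boundary proportions are replaced by
#' (x + 0.5) / (n + 1), where x is the (possibly reconstructed) positive
#' count; interior proportions pass through unchanged. This Anscombe-style
#' correction keeps the probit likelihood finite while leaving ordinary
#' observations untouched.
#'
#' @param prevalence observed proportion(s) in \[0, 1\].
#' @param n number(s) examined (positive).
#' @return Corrected proportion(s), strictly inside (0, 1).
#' @export
correctedPrevalence <- function(prevalence, n) {
  stopifnot(all(n >= 1), all(prevalence >= 0 & prevalence <= 1))
  x <- prevalence * n
  ifelse(prevalence <= 0 | prevalence >= 1, (x + 0.5) / (n + 1), prevalence)
}

#' Sampling variance of a probit-transformed prevalence
#'
#' Delta-method variance of probit(p-hat): var(p-hat) / phi(probit(p))^2,
#' evaluated at the continuity-corrected prevalence.
#'
#' @param prevalence observed proportion(s).
#' @param n number(s) examined.
#' @param se optional standard error(s) of the prevalence on the proportion
#'   scale; when `NULL` the binomial value sqrt(p(1-p)/n) is used.
#' @return Variance(s) on the probit scale.
#' @export
probitSamplingVar <- function(prevalence, n, se = NULL) {
  pc <- correctedPrevalence(prevalence, n)
  if (is.null(se)) se <- sqrt(pc * (1 - pc) / n)
  (se / stats::dnorm(stats::qnorm(pc)))^2
}

# deterministic 32-bit substream seed from (seed, index); keeps per-study
# random streams independent of iteration order
substreamSeed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  for (k in c(index + 1, 7)) {
    s <- (s * 69069 + k * 104729) %% 2147483647
  }
  as.integer(s)
}
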