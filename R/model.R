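#' General time-reversible substitution model with discrete-gamma rates
#'
#' Builds a GTR rate matrix from six exchangeabilities (order AC, AG, AT,
#' CG, CT, GT; GT is conventionally fixed to 1 for identifiability) and
#' base frequencies, scaled so the mean substitution rate is 1 (branch
#' lengths are then substitutions/site). Among-site rate variation uses a
#' discrete gamma with `n_categories` equiprobable categories whose rates
#' are the bin means (shape `alpha`). The transition/transversion ratio
#' implied by the rates and frequencies is stored as `ts_tv`.
#'
#' @param rates Numeric(6): exchangeabilities AC, AG, AT, CG, CT, GT.
#' @param pi Base frequencies (A, C, G, T), summing to 1.
#' @param alpha Gamma shape (> 0); `Inf` disables rate variation.
#' @param n_categories Number of discrete gamma categories (default 4).
#' @return Object of class `substitution_model`.
#' @export
substitution_model <- function(rates = c(1, 1, 1, 1, 1, 1),
                               pi = rep(0.25, 4), alpha = Inf,
                               n_categories = 4L) {
  stopifnot(length(rates) == 6, all(rates >= 0), length(pi) == 4,
            all(pi > 0), alpha > 0)
  pi <- pi / sum(pi)
  names(pi) <- c("A", "C", "G", "T")
  R <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  R["A", "C"] <- rates[1]; R["A", "G"] <- rates[2]; R["A", "T"] <- rates[3]
  R["C", "G"] <- rates[4]; R["C", "T"] <- rates[5]; R["G", "T"] <- rates[6]
  R <- R + t(R)
  Q <- R %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- dimnames(R)
  ts <- pi["A"] * pi["G"] * rates[2] + pi["C"] * pi["T"] * rates[5]
  tv <- pi["A"] * pi["C"] * rates[1] + pi["A"] * pi["T"] * rates[3] +
        pi["C"] * pi["G"] * rates[4] + pi["G"] * pi["T"] * rates[6]
  # eigen-decomposition via symmetrization (Q reversible):
  # B = D^{1/2} Q D^{-1/2} is symmetric with real eigensystem
  sq <- sqrt(pi)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(
    rates = rates, pi = pi, alpha = alpha,
    n_categories = as.integer(n_categories),
    Q = Q, ts_tv = unname(ts / tv),
    eig = list(values = es$values,
               right = diag(1 / sq) %*% es$vectors,
               left = t(es$vectors) %*% diag(sq)),
    gamma_rates = discrete_gamma_rates(alpha, n_categories)),
    class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("<substitution_model> GTR",
      if (is.finite(x$alpha)) paste0("+G(alpha=", signif(x$alpha, 4),
                                     ", ", x$n_categories, " cat)") else "",
      "\n  rates (AC AG AT CG CT GT): ",
      paste(signif(x$rates, 4), collapse = " "),
      "\n  pi: ", paste(signif(x$pi, 4), collapse = " "),
      "\n  Ts/Tv: ", signif(x$ts_tv, 4), "\n", sep = "")
  invisible(x)
}

#' Jukes-Cantor convenience model
#' @param alpha Gamma shape (default `Inf`, no rate variation).
#' @param n_categories Discrete gamma categories.
#' @export
jc_model <- function(alpha = Inf, n_categories = 4L) {
  substitution_model(alpha = alpha, n_categories = n_categories)
}

# mean rate of each of K equiprobable gamma bins, shape = rate = alpha
# (mean-of-quantile-bin discretisation)
discrete_gamma_rates <- function(alpha, K) {
  if (is.infinite(alpha) || K == 1L) return(1)
  b <- qgamma(seq_len(K - 1) / K, shape = alpha, rate = alpha)
  p <- pgamma(c(0, b, Inf), shape = alpha + 1, rate = alpha)
  K * diff(p)
}

#' Transition probability matrix P(t)
#'
#' @param model A [substitution_model()].
#' @param t Branch length (expected substitutions/site, >= 0).
#' @param rate Rate multiplier (gamma category rate).
#' @return 4x4 matrix; rows sum to 1. Tiny negative entries from the
#'   eigen-reconstruction are clamped at 0.
#' @export
prob_matrix <- function(model, t, rate = 1) {
  e <- model$eig
  P <- e$right %*% (exp(e$values * t * rate) * e$left)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(model$Q)
  P
}
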