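#' Empirical amino-acid substitution model
#'
#' Builds a reversible amino-acid substitution model from published
#' exchangeabilities and equilibrium frequencies (WAG or JTT), optionally with
#' a proportion of invariant sites (`+I`) and discrete-gamma rate
#' heterogeneity (`+G`).  The instantaneous rate matrix is scaled so that the
#' expected substitution rate at equilibrium is 1, i.e. branch lengths are in
#' expected substitutions per site.
#'
#' @param name `"WAG"` or `"JTT"`.
#' @param alpha Gamma shape parameter (> 0), or `NA` for no rate
#'   heterogeneity.
#' @param p_inv Proportion of invariant sites in `[0, 1)`, or `NA` for none.
#' @param n_cat Number of discrete gamma categories (>= 1).
#' @param frequencies Optional replacement equilibrium frequencies (length 20,
#'   summing to 1, PAML residue order `A R N D C Q E G H I L K M F P S T W Y V`).
#' @return An object of class `subst_model` with the scaled rate matrix `Q`,
#'   its eigensystem, frequencies `pi`, and rate-heterogeneity parameters.
#' @export
substitution_model <- function(name = c("WAG", "JTT"), alpha = NA, p_inv = NA,
                               n_cat = 4L, frequencies = NULL) {
  name <- match.arg(name)
  exch <- switch(name, WAG = .wag_exch, JTT = .jtt_exch)
  pi <- frequencies %||% switch(name, WAG = .wag_freq, JTT = .jtt_freq)
  pi <- pi / sum(pi)
  if (!is.na(alpha) && alpha <= 0) stop_ctx("alpha must be positive")
  if (!is.na(p_inv) && (p_inv < 0 || p_inv >= 1)) {
    stop_ctx("p_inv must lie in [0, 1)")
  }
  Q <- exch %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))       # expected rate at equilibrium
  Q <- Q / mu
  # Reversible Q: symmetrize with pi^(1/2) for a stable eigendecomposition.
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- diag(1 / sp) %*% es$vectors       # Q = V diag(lambda) Vinv
  Vinv <- t(es$vectors) %*% diag(sp)
  structure(list(name = name, exchangeabilities = exch, pi = pi, Q = Q,
                 V = V, Vinv = Vinv, lambda = es$values,
                 alpha = alpha, p_inv = p_inv, n_cat = as.integer(n_cat)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("subst_model: %s%s%s (%d gamma categories)\n", x$name,
              if (!is.na(x$p_inv)) sprintf(" +I(p=%.3g)", x$p_inv) else "",
              if (!is.na(x$alpha)) sprintf(" +G(alpha=%.3g)", x$alpha) else "",
              x$n_cat))
  invisible(x)
}

# Update rate-heterogeneity parameters without redoing the eigendecomposition.
set_rate_params <- function(model, alpha = model$alpha, p_inv = model$p_inv,
                            n_cat = model$n_cat) {
  model$alpha <- alpha
  model$p_inv <- p_inv
  model$n_cat <- as.integer(n_cat)
  model
}

#' Discrete-gamma rate categories
#'
#' Discretizes a mean-1 gamma distribution (shape = rate = `alpha`) into
#' `n_cat` equal-probability categories, each represented by its conditional
#' mean, renormalized so the category mean is exactly 1.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param n_cat Number of categories (>= 1).
#' @return Strictly increasing numeric vector of `n_cat` rates with mean 1.
#' @export
discretize_gamma <- function(alpha, n_cat) {
  if (!is.finite(alpha) || alpha <= 0) stop_ctx("alpha must be positive")
  n_cat <- as.integer(n_cat)
  if (n_cat < 1L) stop_ctx("n_cat must be >= 1")
  if (n_cat == 1L) return(1)
  p <- seq(0, 1, length.out = n_cat + 1L)
  q <- qgamma(p, shape = alpha, rate = alpha)
  # E[X | q_k <= X < q_{k+1}] for X ~ Gamma(alpha, alpha), via the identity
  # integral x f(x) dx = P(alpha + 1) increments (mean of X is 1).
  cdf1 <- pgamma(q, shape = alpha + 1, rate = alpha)
  rates <- diff(cdf1) * n_cat
  rates / mean(rates)
}

# Rates/weights of the gamma mixture for a model ((1) if no +G).
model_rates <- function(model, n_cat = model$n_cat) {
  if (is.na(model$alpha)) 1 else discretize_gamma(model$alpha, n_cat)
}

# Transition probability matrix P(t) for the scaled rate matrix.
transition_prob <- function(model, t) {
  if (t == 0) return(diag(20))
  P <- model$V %*% (exp(model$lambda * t) * model$Vinv)
  P[P < 0] <- 0
  P
}
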