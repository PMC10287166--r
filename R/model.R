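.model_cache <- new.env(parent = emptyenv())

# Pull an empirical amino-acid model (exchangeabilities + frequencies) out of
# phangorn through its public pml() interface, so the matrices stay in sync
# with the installed phangorn version.
empirical_aa_params <- function(name = "WAG") {
  key <- paste0("params_", name)
  if (!is.null(.model_cache[[key]])) return(.model_cache[[key]])
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  dat <- matrix(c("A", "R"), nrow = 2, dimnames = list(c("A", "B"), NULL))
  fit <- phangorn::pml(tr, phangorn::phyDat(dat, type = "AA"), model = name)
  s <- matrix(0, 20, 20, dimnames = list(AA_LEVELS, AA_LEVELS))
  s[lower.tri(s)] <- fit$Q
  s <- s + t(s)
  pi <- setNames(as.numeric(fit$bf), AA_LEVELS)
  out <- list(s = s, pi = pi)
  .model_cache[[key]] <- out
  out
}

#' Amino-acid substitution model with discrete-gamma rate heterogeneity
#'
#' Builds a reversible WAG (or other empirical) rate matrix with equilibrium
#' frequencies, normalized to mean rate 1, together with `n_cat` discrete
#' gamma rate categories (equal probability, mean-normalized). Transition
#' probabilities are computed from the spectral decomposition of the
#' pi-symmetrized rate matrix.
#'
#' @param name Empirical model name understood by phangorn (default "WAG").
#' @param alpha Gamma shape parameter (> 0, default 1).
#' @param n_cat Number of discrete gamma categories (default 4).
#' @param frequencies Optional replacement equilibrium frequencies (length 20,
#'   sums to 1); default: the model's own empirical frequencies.
#' @return Object of class `aa_model` with elements `pi`, `rates`, `V`,
#'   `Vinv`, `lambda` (eigenvalues) and the normalized rate matrix `Q`.
#' @export
aa_model <- function(name = "WAG", alpha = 1, n_cat = 4, frequencies = NULL) {
  stopifnot(alpha > 0, n_cat >= 1)
  par <- empirical_aa_params(name)
  pi <- if (is.null(frequencies)) par$pi else {
    stopifnot(length(frequencies) == 20, abs(sum(frequencies) - 1) < 1e-6)
    setNames(as.numeric(frequencies) / sum(frequencies), AA_LEVELS)
  }
  Q <- par$s %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * pi)          # mean substitution rate = 1
  # pi-symmetrization keeps the eigenproblem symmetric and stable
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  V <- diag(1 / sp) %*% eig$vectors
  Vinv <- t(eig$vectors) %*% diag(sp)
  rates <- if (n_cat == 1) 1 else phangorn::discrete.gamma(alpha, n_cat)
  structure(list(name = name, pi = pi, Q = Q, alpha = alpha,
                 rates = as.numeric(rates), n_cat = as.integer(n_cat),
                 V = V, Vinv = Vinv, lambda = eig$values),
            class = "aa_model")
}

#' @export
print.aa_model <- function(x, ...) {
  cat("<aa_model> ", x$name, " + Gamma(alpha = ", x$alpha, ", ",
      x$n_cat, " categories)\n", sep = "")
  invisible(x)
}

#' Transition probability matrix P(t) for one rate category
#' @param model An `aa_model`.
#' @param t Branch length (expected substitutions/site at rate 1).
#' @param rate Rate multiplier (default 1).
#' @return 20 x 20 row-stochastic matrix.
#' @export
prob_matrix <- function(model, t, rate = 1) {
  stopifnot(t >= 0, rate >= 0)
  model$V %*% (exp(model$lambda * t * rate) * model$Vinv)
}
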