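# Independent brute-force oracles used by several test files.

# direct two-Gaussian marginal likelihood ratio (the quantity the Wakefield
# shrinkage formula re-expresses)
.abf_oracle <- function(beta, se, prior_sd) {
  dnorm(beta, 0, sqrt(se^2 + prior_sd^2), log = TRUE) -
    dnorm(beta, 0, se, log = TRUE)
}

# exhaustive enumeration of every causal-variant configuration for small J
.coloc_oracle <- function(d1, d2, priors, sd1, sd2) {
  J <- length(d1$beta)
  a1 <- exp(.abf_oracle(d1$beta, d1$se, sd1))
  a2 <- exp(.abf_oracle(d2$beta, d2$se, sd2))
  s <- c(H0 = 1, H1 = 0, H2 = 0, H3 = 0, H4 = 0)
  for (i in seq_len(J)) {
    s["H1"] <- s["H1"] + priors[1] * a1[i]
    s["H2"] <- s["H2"] + priors[2] * a2[i]
    s["H4"] <- s["H4"] + priors[3] * a1[i] * a2[i]
    for (j in seq_len(J)) {
      if (i != j) s["H3"] <- s["H3"] + priors[1] * priors[2] * a1[i] * a2[j]
    }
  }
  s / sum(s)
}
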