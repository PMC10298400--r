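# Shared fixtures and independent oracles used across the suite.

# the worked 4-point fit used throughout: slope 0.5, intercept 0.75,
# rss 1.25, tss 2.5, R^2 0.5, df 2
worked_fit <- function() fit_gene_regression(c(1, 0.5, 2.5, 2), c(0, 1, 2, 3))

# small valid study design built directly from matrices
tiny_design <- function(n1 = 5, n2 = 5, m = 3, seed = 11) {
  set.seed(seed)
  YA <- matrix(rnorm(n1 * m), n1, m,
               dimnames = list(paste0("a", 1:n1), paste0("g", 1:m)))
  YB <- matrix(rnorm(n2 * m), n2, m,
               dimnames = list(paste0("b", 1:n2), paste0("g", 1:m)))
  study_design(contrast_matrix(YA, "A", runif(n1, 1, 15)),
               contrast_matrix(YB, "B", runif(n2, 1, 15)))
}

# a random non-degenerate gene fit
random_fit <- function(n = NULL) {
  if (is.null(n)) n <- sample(4:40, 1)
  a <- runif(n, 0.5, 16)
  y <- rnorm(1, 0, 2) + rnorm(1, 0, 1) * a + rnorm(n, 0, runif(1, 0.2, 3))
  fit_gene_regression(y, a)
}

# independent reference fit via stats::lm
lm_oracle <- function(y, a) {
  sm <- summary(stats::lm(y ~ a))
  list(intercept = unname(sm$coefficients["(Intercept)", "Estimate"]),
       slope = unname(sm$coefficients["a", "Estimate"]),
       intercept_se = unname(sm$coefficients["(Intercept)", "Std. Error"]),
       t_intercept = unname(sm$coefficients["(Intercept)", "t value"]),
       p_intercept = unname(sm$coefficients["(Intercept)", "Pr(>|t|)"]),
       r_squared = sm$r.squared)
}

# brute-force multiplicity oracles: plain threshold scan, and the literal
# step-up definition (largest k with p_(k) <= k * level / m, reject all
# p <= p_(k))
brute_bonferroni <- function(p, level) which(p <= level / length(p))
brute_bh <- function(p, level) {
  m <- length(p)
  if (m == 0) return(integer(0))
  sp <- sort(p)
  ok <- which(sp <= seq_len(m) * level / m)
  if (!length(ok)) return(integer(0))
  which(p <= sp[max(ok)])
}

# random p-vector generator with ties, zeros and ones
random_pvec <- function(max_len = 20) {
  m <- sample(1:max_len, 1)
  p <- runif(m)
  if (m > 2 && runif(1) < 0.5) p[sample(m, 2)] <- p[sample(m, 1)]  # ties
  if (runif(1) < 0.3) p[sample(m, 1)] <- 0
  if (runif(1) < 0.3) p[sample(m, 1)] <- 1
  p
}

expect_rel_equal <- function(x, y, tol) {
  expect_true(all(abs(x - y) <= tol * pmax(abs(y), 1e-300)),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(x - y) / pmax(abs(y), 1e-300)), tol))
}
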