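# shared fixture builders for the test suite

geo4 <- function() burst_model("geometric", 4)

single_gene <- function(steady_state = 1000, alpha = 1 - exp(-2),
                        burst = geo4()) {
  gene_spec(burst, steady_state = steady_state, relative_threshold = alpha)
}

# random relative-threshold vector satisfying the fixed-mean constraint
# prod(1 - alpha_i) = exp(-gammaT): split gammaT by a Dirichlet draw
random_feasible_alphas <- function(n, gammaT) {
  g <- stats::rgamma(n, shape = 1)
  1 - exp(-gammaT * g / sum(g))
}
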