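# shared fixtures for the suite

default_params <- nfkb_params()

# equilibrium of the default model at a given TR, seeded by integration
settle_equilibrium <- function(TR, params = default_params,
                               t_settle = 3e4) {
  sys <- set_par(nfkb_system(params), "TR", TR)
  find_equilibrium(sys, nfkb_initial_state(params),
                   integrate_fallback = TRUE, t_settle = t_settle)
}

# random physical reduced states for derivative checks
random_states <- function(n, params = default_params, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    ikk <- params$totalIKK * runif(2, 0.05, 0.4)
    nf <- params$totalNFkB * runif(4, 0.02, 0.2)
    c(ikk[1], ikk[2],                 # IKKn, IKK
      runif(2, 1e-4, 0.05),          # IkBa, IkBan
      nf[1], nf[2], nf[3], nf[4],    # NFkB, NFkBn, IkBaNFkBn, pIkBaNFkB
      runif(1, 1e-4, 0.05),          # A20
      runif(2, 1e-6, 1e-3))          # A20t, IkBat
  })
}
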