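# Shared fixtures and independent oracles.

# Working parameters of the reference system: a 15-bp DNA duplex titrated in
# a 20 mM Na+ buffer, SI units internally.
ref <- list(
  D_f = 1.251e-9,      # free Na+ diffusion, m^2/s
  D_b = 0.71e-9,       # ion-atmosphere Na+ diffusion, m^2/s
  a = 25.5,            # atmosphere Na+ per duplex
  Na_buffer = 0.020,   # mol/L
  Q = 0.58,            # Na+/K+ preference quotient
  R_f = 17.3,          # free-state R2, s^-1
  R_b = 73,            # atmosphere R2, s^-1
  C_M_max = 1.74e-3    # highest duplex concentration, mol/L
)
ref$Na_total <- ref$Na_buffer + ref$a * ref$C_M_max  # 64.37 mM
ref$T_cap <- ref$a * ref$C_M_max                     # 44.37 mM

ref_pulse <- function() pulse_params(delta = 2e-3, Delta = 20e-3, tau = 0.2e-3,
                                     nucleus = "23Na")

# Independent bisection solver for the competition equilibrium, working from
# the primitive equilibrium Q = (N_b K_f)/(N_f K_b) with the three mass
# balances, not from the quadratic closed form.
bisect_bound <- function(Na, K, T_cap, Q, tol = 1e-15) {
  if (K == 0) return(T_cap)
  if (T_cap == 0) return(0)
  f <- function(Nb) {
    Kb <- T_cap - Nb
    Nf <- Na - Nb
    Kf <- K - Kb
    Nb * Kf - Q * Nf * Kb
  }
  upper <- min(T_cap, Na)
  stats::uniroot(f, c(0, upper), tol = tol)$root
}

# Brute-force grid argmin for one-parameter least squares.
grid_argmin <- function(grid, loss) grid[which.min(vapply(grid, loss, numeric(1)))]
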