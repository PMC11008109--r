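# Shared constructors for the test suite.

# dimensionless parameter point (tau_B = 1 s unit)
dim_params <- function(tau_ratio = 1/6, beta = 0.5, v = 1, omega = 5, ...) {
  fcs_params_dimensionless(tau_ratio, beta, v, omega = omega, ...)
}

# physical parameter set obeying detailed balance: C_C = (k_plus/k_minus) C_A C_B
phys_params <- function(k_plus = 10, k_minus = 1e3, C_A = 50, C_B = 20,
                        D = 50, D_B = 470, L = 0.2, H = 1,
                        Q_B = 1, Q_C = 1.5) {
  fcs_params(k_plus, k_minus, C_A, C_B, C_C = k_plus / k_minus * C_A * C_B,
             D, D_B, L, H, Q_B, Q_C)
}

# default log time grid in units of tau_B
chi_grid <- function(n = 48, lo = -2, hi = 3) 10^seq(lo, hi, length.out = n)
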