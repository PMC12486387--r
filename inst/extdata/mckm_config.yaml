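# Canonical model configuration.
#
# constants:
#   alpha_glc  lactate-switch glucose threshold [g/L]; the shipped value is
#              a plausible depletion-scale stand-in, override with a
#              data-derived estimate when available
#   glc_F_in   glucose concentration of the bolus feed [g/L] (synthetic
#              schedule: sized so one 0.5 mL bolus raises a 15 mL culture
#              by roughly 3 g/L)
#   glu_F_in   glutamate concentration of the bolus feed [mM]
#   V0         initial working volume [L]
#
# bounds: the shipped regression box and default initial guesses; mu_max
# and K_glc initial guesses are normally recomputed per run by the Monod
# pre-regression and are listed here only as fallbacks.
constants:
  alpha_glc: 0.5
  glc_F_in: 100.0
  glu_F_in: 50.0
  V0: 0.015
bounds:
  lb:
    mu_max: 0.01
    k_d: 0.0001
    K_glc: 0.1
    Y_X_glc: 0.1
    Y_X_gln: 0.1
    Y_X_glu: 0.001
    Y_lac_glc: 0.1
    Y_X_amm: 0.1
    Y_gln_glu: 0.001
    Y_P_X: 0.0001
    Y_X_lac: 0.01
    m_glc: 0.0
    KD_amm: 0.0
  ub:
    mu_max: 0.1
    k_d: 0.1
    K_glc: 10.0
    Y_X_glc: 10.0
    Y_X_gln: 10.0
    Y_X_glu: 20.0
    Y_lac_glc: 2.0
    Y_X_amm: 20.0
    Y_gln_glu: 1.0
    Y_P_X: 1.0
    Y_X_lac: 5.0
    m_glc: 1.0
    KD_amm: 100.0
  ig:
    mu_max: 0.0316
    k_d: 0.016
    K_glc: 1.0
    Y_X_glc: 1.0
    Y_X_gln: 0.974
    Y_X_glu: 1.0
    Y_lac_glc: 0.615
    Y_X_amm: 0.67
    Y_gln_glu: 0.7
    Y_P_X: 0.2
    Y_X_lac: 2.7
    m_glc: 0.006192
    KD_amm: 5.0
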