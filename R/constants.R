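# Fire-weather index constants, collected in one place with provenance.
# All coefficients are from the published formulations cited below and
# are never repeated inline elsewhere in the package.
#
# FFDI  : McArthur Mark 5 forest fire danger meter, equation form of
#         Noble, Bary & Gill (1980), Aust. J. Ecol. 5, 201-203.
# KBDI  : Keetch & Byram (1968) drought index, SI (mm) formulation as
#         used operationally in Australia (Finkele et al. 2006, BMRC).
# DF    : Griffiths (1999) drought factor, Aust. For. 62, 202-206,
#         limiting form driven by KBDI and the most recent significant
#         rain event.
# CH    : Continuous Haines index, Mills & McCaw (2010), CAWCR Tech.
#         Rep. 20 (stability term from the 850-700 hPa lapse, humidity
#         term from the 850 hPa dewpoint depression).

ft_const <- list(
  ffdi = list(
    scale   = 2.0,      # FFDI = scale * exp(...)
    a0      = -0.450,
    a_lndf  = 0.987,    # coefficient on ln(drought factor)
    a_rh    = -0.0345,  # per % relative humidity
    a_t     = 0.0338,   # per deg C
    a_v     = 0.0234    # per km/h 10 m wind speed
  ),
  kbdi = list(
    max_mm        = 203.2,   # 8 inches soil moisture capacity
    interception  = 5.08,    # mm absorbed per rain event before runoff to the index
    et_c1         = 0.968,
    et_c2         = 0.0875,  # per deg C
    et_c3         = 1.5552,
    et_c4         = 8.30,
    et_d1         = 10.88,
    et_d2         = 0.001736 # per mm mean annual rainfall
  ),
  df = list(
    cap        = 10.0,
    k1         = 10.5,
    k2         = 30.0,   # KBDI offset in the availability term
    k3         = 40.0,   # KBDI scale in the availability term
    x_n_exp    = 1.3,    # exponent on days since rain
    event_mm   = 2.0,    # minimum rainfall of a significant rain event
    r1         = 41.0, r2 = 40.0 # rational-polynomial shape constants
  ),
  chaines = list(
    ca_scale  = 0.5,  # stability: 0.5 * (T850 - T700) - 2
    ca_offset = 2.0,
    cb_scale  = 1 / 3, # humidity: DD/3 - 1, DD capped at 30 deg C
    cb_offset = 1.0,
    dd_cap    = 30.0,
    cb_knee   = 5.0    # CB excess above the knee is halved
  ),
  dry_lightning_rain_mm = 2.5
)
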