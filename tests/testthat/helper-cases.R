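# Shared small fixtures.  Expensive objects are built once per test run and
# memoized here; penalty stiffnesses are set explicitly where the exact
# calibrated value is immaterial to the property under test.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small low-Re chain (zebrafish-like geometry, reduced N)
small_case <- function(N = 10, B_over_L = 0.125, f = 20) {
  params <- physical_params(L = 1, N = N, r = 0.05, E = 0.7e6)
  params$k_spring <- 2e4
  drag <- drag_spec("lighthill", params, wavelength = 1)
  act <- activation_spec("traveling_wave", B = B_over_L, f = f,
                         wavelength = 1)
  list(params = params, drag = drag, act = act, wavespeed = f * 1)
}

# calibrated full zebrafish configuration, shared by the acceptance tests
zf_calibrated <- function() {
  memo("zf_params", {
    case <- zebrafish_case()
    calibrate_k_spring(case$params, case$drag, case$act,
                       method = "bdf", rtol = 1e-5, atol = 1e-7)
  })
}

zf_runs <- function() {
  memo("zf_runs", {
    run_zebrafish(params = zf_calibrated())
  })
}

# calibrated intermediate-Re validation configuration
val_calibrated <- function() {
  memo("val_params", {
    case <- validation_case()
    calibrate_k_spring(case$params, case$drag, case$act, n_periods = 2)
  })
}

# flatten a chain_state into the trajectory row layout
state_to_vec_t <- function(st) swimchain:::state_to_vec(st)
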