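# Shared, lazily computed fixtures.  Events and maps are expensive (seconds
# to a minute each), so they are computed once per test run and reused by
# the module tests and the acceptance suite alike.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fx_params <- function() fixture("params", build_default_params())

fx_ctx12 <- function() fixture("ctx12", circadian_context(12, "natural"))

# preictal steady state at the ZT12 transition context
fx_steady12 <- function() fixture("steady12", {
  run_to_steady(fx_params(), drive_input(), max_s = 90)
})

# oscillatory event: irregular in both phases (central region of the joint map)
fx_trace5 <- function() fixture("trace5", {
  simulate_event(seizure_protocol(Si = 1.2, Pi = 0.1, Sp = -1, Pp = 2.0),
                 fx_ctx12(), fx_params(), init_state = fx_steady12())
})

# asystolic event: no firing in either sampled window
fx_trace9 <- function() fixture("trace9", {
  simulate_event(seizure_protocol(Si = 2.0, Pi = 0.1, Sp = -1, Pp = 3.8),
                 fx_ctx12(), fx_params(), init_state = fx_steady12())
})

# mild event: rhythmic in both phases
fx_trace1 <- function() fixture("trace1", {
  simulate_event(seizure_protocol(Si = 0.4, Pi = 0.1, Sp = -1, Pp = 0.8),
                 fx_ctx12(), fx_params(), init_state = fx_steady12())
})

# null protocol: no perturbation at all
fx_trace_null <- function() fixture("trace_null", {
  simulate_event(seizure_protocol(Si = 0, Pi = 0, Sp = 0, Pp = 0),
                 fx_ctx12(), fx_params(), init_state = fx_steady12())
})

# reduced-resolution parameter maps for the circadian/vigilance comparisons
fx_map <- function(type, zt, vigilance) {
  key <- paste("map", type, zt, vigilance, sep = "_")
  fixture(key, {
    run_map(build_grid(type, 8), circadian_context(zt, vigilance),
            fx_params())
  })
}

random_valid_state <- function() {
  s <- c(V = runif(1, -80, 40),
         d_L = runif(1), f_L = runif(1), f_Ca = runif(1),
         d_T = runif(1), f_T = runif(1), y = runif(1), n = runif(1),
         Nai = runif(1, 4, 16), Cai = runif(1, 5e-5, 5e-3),
         pka = runif(1, 0, 4))
  s
}

random_drive <- function() {
  drive_input(sna = runif(1, 0, 3.5), pna = runif(1, 0, 6),
              bt = runif(1, 34, 40), lcr = runif(1, 0.5, 1.5))
}
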