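# Shared fixtures built in code.

# a noiseless trace with a given steady-state voltage and LED current,
# independent of the simulator (ramp samples deliberately absurd so any
# leakage into V_avg is caught)
make_flat_trace <- function(i_led, v_steady, ramp = 100,
                            egg_id = "eggX", day = 10) {
  structure(
    list(egg_id = egg_id, day = as.integer(day), i_led = i_led,
         samples = c(rep(ramp, 10), rep(v_steady, 290)),
         sample_rate = 33.3, flag = "ok"),
    class = "sensor_trace")
}

# noise-free opacity series from a growth model on days 6..16
model_series <- function(model, days = 6:16) {
  data.frame(day = days, opacity = predict(model, days))
}

tiny_config <- function(...) {
  cohort_config(n_eggs = 5, seed = 11, ...)
}
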