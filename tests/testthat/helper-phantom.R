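# Shared phantom fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

moving_phantom <- function() cached("moving", generate_phantom(phantom_spec()))

static_phantom <- function() {
  cached("static", generate_phantom(phantom_spec(motion_amplitude_mm = 0)))
}

moving_case <- function() {
  cached("moving_case", {
    ph <- moving_phantom()
    build_case(ph$phases, ph$gtv, ph$oars)
  })
}

static_case <- function() {
  cached("static_case", {
    ph <- static_phantom()
    build_case(ph$phases, ph$gtv, ph$oars)
  })
}

# coarse angular grid used wherever a full map is computed in tests
test_grid <- function() beam_grid(gantry_step = 30, couch_step = 45)

moving_maps <- function() {
  cached("moving_maps", compute_metric_maps(moving_case(), test_grid()))
}
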