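# Small builders shared across tests.

# a minimal two-beam AP/PA plan around one in-field point
make_ap_pa_plan <- function(dmax_gy = 2, fs = 10, tray = FALSE) {
  beams <- list(
    beam_spec("ant", "megavoltage", equivalent_square = fs, tray = tray,
              dmax_dose_gy = dmax_gy, exit_thickness_cm = 20),
    beam_spec("post", "megavoltage", equivalent_square = fs, tray = tray,
              dmax_dose_gy = dmax_gy, exit_thickness_cm = 20)
  )
  points <- list(
    point_spec("center",
      ant = point_location("in_field", "entrance"),
      post = point_location("in_field", "exit", depth_cm = 20))
  )
  list(beams = beams, points = points)
}

# simple linear PDD over 1.5-30 cm for exit-side lookups in plan tests
make_test_pdd <- function(beam = "megavoltage") {
  pdd_table(depths = c(1.5, 10, 20, 30), values = c(100, 70, 45, 28),
            beam = beam)
}

# write a plan config to a temp yaml file and return its path
write_temp_plan <- function(plan_list) {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(plan_list, path)
  path
}
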