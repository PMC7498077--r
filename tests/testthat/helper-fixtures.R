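# Fixtures built in code: degenerate (zero-variance) parameter databases
# give fully predictable plants for topology and counting tests.

point_mass <- function(x) dist_normal(x, 0)

root_specs <- function(axial, count, h_g = 30, len = 150, deflection = 0) {
  list(axial_angle_deg = point_mass(axial),
       radial_angle_deg = point_mass(0),
       initial_radius_mm = point_mass(1.5),
       tip_radius_mm = point_mass(0.5),
       length_mm = point_mass(len),
       depth_mm = point_mass(100),
       total_deflection_deg = point_mass(deflection),
       count = point_mass(count),
       distance_to_seed_mm = point_mass(h_g))
}

make_degenerate_db <- function(n_sem = 2, n_cr = 2, n_cs = 1, n_k = 1) {
  new_parameter_db("Zaodabai", list(
    seed_potato = list(length_mm = point_mass(60), width_mm = point_mass(45),
                       height_mm = point_mass(35),
                       burial_depth_mm = point_mass(80)),
    underground_stem = list(bottom_radius_mm = point_mass(6),
                            top_radius_mm = point_mass(4.5),
                            height_mm = point_mass(80)),
    seminal_root = root_specs(150, n_sem, h_g = 0),
    creeping_root = root_specs(110, n_cr),
    creeping_stem = root_specs(100, n_cs, h_g = 25, len = 120),
    tuber = list(length_mm = point_mass(75), width_mm = point_mass(58),
                 height_mm = point_mass(48), count = point_mass(n_k))))
}

# Brute-force cumulative-sum walk: the independent oracle for inverse-CDF
# interval selection.
walk_select <- function(probs, u) {
  cum <- 0
  for (i in seq_along(probs)) {
    if (u > cum && u <= cum + probs[i]) return(i)
    cum <- cum + probs[i]
  }
  if (u == 0) 1L else length(probs)
}
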