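# Shared fixtures, built in code.

# A rabbit model with a hepatically cleared compound (linear kinetics).
test_compound <- function(...) {
  compound("testdrug", molecular_weight = 200, logP = 0.5,
           fraction_unbound_plasma = 0.7,
           specific_hepatic_clearance = 0.4, ...)
}

test_model_iv <- function(dose = 5) {
  build_model(species_template("rabbit"), test_compound(),
              admin_protocol("iv_bolus", dose))
}

# Exactly-degenerate configuration: essentially all volume sits in the
# venous pool, every other compartment is vanishingly small and acts as a
# quasi-steady slave, and elimination is glomerular filtration only. The
# venous plasma concentration then follows (D/V) exp(-k t) with
# k = specific_gfr * V_kidney / V_venous (fu = 1, BP = 1, all Kp = 1).
one_compartment_fixture <- function(k = 0.005, v_ven = 0.96, eps = 1e-8) {
  comp <- composition(0.92, 0, 0)
  organs <- lapply(ORGAN_ORDER, function(o)
    organ_spec(o, volume = eps, specific_blood_flow = 1e6,
               cellular_composition = comp, intracellular_pH = 7.4,
               fraction_vascular = 0, fraction_interstitial = 0,
               peripheral_blood_flow_fraction = if (o == "muscle") 1 else 0,
               drains_to = if (o %in% c("spleen", "stomach_wall",
                                        "small_intestine_wall",
                                        "large_intestine_wall"))
                 "portal" else "venous"))
  names(organs) <- ORGAN_ORDER
  lumen <- lapply(LUMEN_ORDER, function(s)
    git_segment(s, length = 1, proximal_radius = 0.1, distal_radius = 0.1,
                surface_enhancement_factor = 1, pH = 7.4,
                fill_fraction = 0.5))
  names(lumen) <- LUMEN_ORDER
  bw <- v_ven + (length(organs) + 2) * eps
  sp <- species_physiology(
    name = "onecomp", body_weight = bw, haematocrit = 0.45,
    plasma_pH = 7.4, rbc_pH = 7.4,
    plasma_composition = comp, interstitial_composition = comp,
    rbc_composition = comp, organs = organs, lumen = lumen,
    gastric_emptying_time = 15, small_intestinal_transit_time = 90,
    large_intestinal_transit_time = 600,
    specific_gfr = k * v_ven / eps,
    blood_volumes = list(venous = v_ven, arterial = eps, portal = eps))
  cmp <- compound("tracer", molecular_weight = 200, logP = 0,
                  fraction_unbound_plasma = 1, gfr_fraction = 1)
  proto <- admin_protocol("iv_bolus", 10)
  list(species = sp, compound = cmp, protocol = proto,
       V = v_ven, k = k,
       dose_umol = 10 * bw / 200 * 1000)
}

# Rabbit physiology with every compartment composition and pH identical
# to plasma: all partition coefficients collapse to 1.
uniform_species <- function() {
  sp <- species_template("rabbit")
  comp <- sp$plasma_composition
  sp$interstitial_composition <- comp
  sp$rbc_composition <- comp
  sp$rbc_pH <- sp$plasma_pH
  for (o in names(sp$organs)) {
    sp$organs[[o]]$cellular_composition <- comp
    sp$organs[[o]]$intracellular_pH <- sp$plasma_pH
  }
  sp
}

# constants mirrored from the package internals (not exported)
ORGAN_ORDER <- c("lung", "liver", "kidney", "muscle", "skin", "adipose",
                 "brain", "heart", "gonads", "bone", "spleen",
                 "stomach_wall", "small_intestine_wall",
                 "large_intestine_wall", "rest")
LUMEN_ORDER <- c("stomach", "duodenum", "upper_jejunum", "lower_jejunum",
                 "upper_ileum", "lower_ileum", "caecum", "colon")

lumen_paths_of <- function(model) {
  pp <- model$parameter_paths
  pp[grepl("^Organism\\|Lumen\\|", pp) |
       grepl("intestinal transit time", pp)]
}

# hand-rolled profile for metric tests
make_profile <- function(times, conc, site = observation_site("venous_plasma"),
                         role = "c0") {
  structure(list(site = site, times = times, concentrations = conc,
                 role = role), class = "conc_profile")
}
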