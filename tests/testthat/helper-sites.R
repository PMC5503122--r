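# shared fixtures: tiny parameter sets, hand-built sites, toy populations

# parameter set from key = r0 pairs
make_params <- function(..., b = 0.37) {
  vals <- c(...)
  p <- bv_params(b = b)
  for (k in names(vals)) p <- set_param(p, k, vals[[k]])
  p
}

# homoleptic Fe site with given distances
fe_site <- function(distances, ligand = "N", oxidation = 2, spin = "none",
                    id = "s1", r_factor = 0.03, ...) {
  binding_site("Fe", rep(ligand, length(distances)), distances,
               oxidation = oxidation, spin = spin, entry_id = "E1",
               site_id = id, r_factor = r_factor, ...)
}

# the two published hemoglobin iron sites (printed distances)
deoxy_hb <- function() {
  binding_site("Fe", c(rep("N", 5), "O"),
               c(2.03, 2.06, 2.15, 2.15, 2.16, 3.39),
               oxidation = 2, entry_id = "2hhb", site_id = "FE_A",
               r_factor = 0.05)
}
oxy_hb <- function() {
  binding_site("Fe", rep("N", 6),
               c(1.75, 1.99, 2.00, 2.01, 2.01, 2.26),
               oxidation = 3, entry_id = "1buw", site_id = "FE_A",
               r_factor = 0.05)
}

# single-R0 parameter set that maps both N and O of a site to one value
single_r0_params <- function(r0, metal = "Fe", oxidation = 2,
                             ligands = c("N", "O"), b = 0.37) {
  p <- bv_params(b = b)
  for (lig in ligands) {
    p <- set_param(p, bond_type_key(metal, oxidation, lig), r0)
  }
  p
}

# bisection oracle: the R0 at which a site's BVS equals S (independent of
# the closed form under test)
bisect_r0 <- function(site, params_template, lo = 1.01, hi = 3.4,
                      iters = 200) {
  target <- site$oxidation
  score <- function(r0) {
    p <- params_template
    for (lig in unique(site$contacts$ligand)) {
      p <- set_param(p, bond_type_key(site$metal, site$oxidation, lig), r0)
    }
    bvs(site, p) - target
  }
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (score(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# standard two-ligand-type Fe(III) truth set used across fitting tests
fe3_truth <- function() {
  make_params("Fe3-N" = 1.70, "Fe3-O" = 1.76)
}
fe3_literature_init <- function() {
  make_params("Fe3-N" = 1.86, "Fe3-O" = 1.759)
}
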