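#' Bond valence of a single metal-ligand bond
#'
#' The exponential bond length-valence law: a bond of length `d` carries
#' valence `exp((R0 - d)/b)`. `R0` is the bond-type-specific length at
#' which a single bond has valence exactly 1 and `b` is the global softness
#' parameter, 0.37 Angstrom throughout.
#'
#' @param distance Bond length in Angstrom, > 0 (vectorised).
#' @param r0 Bond-valence parameter `R0` in Angstrom.
#' @param b Softness parameter in Angstrom, > 0.
#' @return Bond valence in valence units.
#' @examples
#' bond_valence(2.03, 1.76, 0.37)  # 0.48 to 2 dp
#' @export
bond_valence <- function(distance, r0, b = 0.37) {
  if (!is.numeric(b) || any(!is.finite(b)) || any(b <= 0)) {
    stop("b must be positive", call. = FALSE)
  }
  if (!is.numeric(distance) || any(!is.finite(distance)) || any(distance <= 0)) {
    stop("distance must be positive", call. = FALSE)
  }
  exp((r0 - distance) / b)
}

#' Bond-valence sum of a site
#'
#' Sums the bond valences of every contact of a site under a parameter set,
#' resolving each contact's bond type (metal, oxidation state, spin class
#' where a split is declared, ligand element). Under the bond-valence sum
#' rule the result should equal the oxidation state of the metal.
#'
#' @param site A `bv_site` with an assigned oxidation state (not needed for
#'   an empty site, whose sum is 0).
#' @param params A `bv_params` resolving every bond type of the site; an
#'   unresolvable type is an error naming the key.
#' @return The bond-valence sum in valence units.
#' @export
bvs <- function(site, params) {
  stopifnot(inherits(site, "bv_site"), inherits(params, "bv_params"))
  if (nrow(site$contacts) == 0L) return(0.0)
  keys <- site_contact_keys(site, params)
  r0 <- vapply(keys, function(k) get_r0(params, k), 0, USE.NAMES = FALSE)
  sum(exp((r0 - site$contacts$distance) / params$b))
}

#' Closed-form R0 of a homoleptic site
#'
#' For a site whose first-sphere ligands are all one element, setting the
#' bond-valence sum equal to the oxidation state `S` yields a unique
#' parameter: `R0 = b * (log(S) - log(sum(exp(-d_j/b))))`. This is the
#' classical route to reference parameters from curated homoleptic
#' complexes; heteroleptic sites have no such closed form and go through
#' [fit_r0()] instead.
#'
#' @param site A homoleptic `bv_site` with assigned oxidation state.
#' @param b Softness parameter in Angstrom.
#' @return `R0` in Angstrom, satisfying `bvs == S` to machine precision.
#' @export
homoleptic_r0 <- function(site, b = 0.37) {
  stopifnot(inherits(site, "bv_site"))
  if (!is_homoleptic(site)) {
    stop("homoleptic_r0 requires a homoleptic site (single ligand element)",
         call. = FALSE)
  }
  if (is.na(site$oxidation)) {
    stop("oxidation state unassigned", call. = FALSE)
  }
  b * (log(site$oxidation) - log(sum(exp(-site$contacts$distance / b))))
}

#' Parameter shift that restores the sum rule for one site
#'
#' The change in a single `R0` parameter that would make the site's
#' bond-valence sum exactly equal its expected oxidation state `S`:
#' `dR0 = b * log(1 + (S - V)/V_beta)`, where `V` is the current sum and
#' `V_beta` the summed valence of the contacts of the shifted bond type.
#' For a homoleptic site this reduces to `b * log(S/V)`. The mean of
#' `dR0^2` over sites is used as an upper bound on the parameter variance
#' (see [bv_uncertainty()]).
#'
#' @param site A `bv_site` with assigned oxidation state.
#' @param params Current parameter set.
#' @param target_type Bond-type key whose `R0` is shifted; the site must
#'   contain at least one contact of that type.
#' @return The shift in Angstrom. Applying it to `target_type` and
#'   recomputing [bvs()] gives `S` exactly.
#' @export
delta_r0 <- function(site, params, target_type) {
  stopifnot(inherits(site, "bv_site"), inherits(params, "bv_params"))
  keys <- site_contact_keys(site, params)
  sel <- keys == target_type
  if (!any(sel)) {
    stop("site has no contact of bond type '", target_type, "'", call. = FALSE)
  }
  r0 <- vapply(keys, function(k) get_r0(params, k), 0, USE.NAMES = FALSE)
  v <- exp((r0 - site$contacts$distance) / params$b)
  v_total <- sum(v)
  v_beta <- sum(v[sel])
  arg <- 1 + (site$oxidation - v_total) / v_beta
  if (arg <= 0) {
    stop("no-feasible-shift: remaining contacts already exceed S (log arg ",
         signif(arg, 3), ") for '", target_type, "'", call. = FALSE)
  }
  params$b * log(arg)
}

#' Typical metal-ligand distance for equal contributions
#'
#' The distance at which `n` equal bond-valence contributions sum exactly to
#' the oxidation state `S`: `d = R0 - b * log(S/n)`. In an octahedral site
#' each ligand should contribute `S/6` valence units; this is the distance
#' that achieves it.
#'
#' @param r0 `R0` in Angstrom.
#' @param oxidation_state Integer oxidation state `S`.
#' @param coordination_number Number of equal contributions `n`, >= 1.
#' @param b Softness parameter in Angstrom.
#' @return Distance in Angstrom.
#' @examples
#' typical_distance(1.57, 2, 6)  # low-spin Fe(II)-N, octahedral: 1.98
#' @export
typical_distance <- function(r0, oxidation_state, coordination_number,
                             b = 0.37) {
  if (any(coordination_number < 1)) {
    stop("coordination_number must be >= 1", call. = FALSE)
  }
  if (any(oxidation_state < 1)) {
    stop("oxidation_state must be >= 1", call. = FALSE)
  }
  r0 - b * log(oxidation_state / coordination_number)
}

#' First-coordination-sphere distance cutoff
#'
#' A contact contributing less than a given fraction of the expected
#' oxidation state is presumed outside the first coordination sphere. The
#' fractional rule inverts to a distance cutoff
#' `d_cutoff = R0 - b * (log(fraction) + log(S))`; at exactly this distance
#' the bond valence equals `fraction * S`. For a divalent cation with the
#' default 5% fraction the cutoff sits about 0.85 Angstrom above `R0`.
#'
#' @param r0 Reference `R0` in Angstrom.
#' @param oxidation_state Integer oxidation state `S`.
#' @param b Softness parameter in Angstrom.
#' @param fraction Contribution fraction in (0, 1); default 0.05.
#' @return Cutoff distance in Angstrom.
#' @export
cutoff_distance <- function(r0, oxidation_state, b = 0.37, fraction = 0.05) {
  if (any(fraction <= 0) || any(fraction >= 1)) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  if (any(oxidation_state < 1)) {
    stop("oxidation_state must be >= 1", call. = FALSE)
  }
  r0 - b * (log(fraction) + log(oxidation_state))
}
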