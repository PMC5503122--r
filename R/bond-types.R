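#' Build a canonical bond-type key
#'
#' A bond type is the unit a single `R0` parameter attaches to: a metal
#' species (element plus integer oxidation state, optionally resolved into a
#' spin class) bonded to one ligand element. Keys are plain strings such as
#' `"Fe2-N"`, `"Fe2:LS-N"` or `"Na1-O"`, so they can index named vectors and
#' survive CSV round trips unchanged.
#'
#' @param metal Metal element symbol (e.g. `"Fe"`).
#' @param oxidation Positive integer oxidation state.
#' @param ligand Ligand element symbol (e.g. `"N"`).
#' @param spin Spin class, one of `"none"`, `"LS"`, `"HS"`. Spin-resolved
#'   keys are only meaningful for bond types where a split has been declared
#'   (in practice Fe-N for both oxidation states).
#' @return A length-1 character key.
#' @examples
#' bond_type_key("Fe", 2, "N", "HS")
#' @export
bond_type_key <- function(metal, oxidation, ligand, spin = "none") {
  stopifnot(is.character(metal), is.character(ligand))
  oxidation <- as.integer(oxidation)
  if (any(is.na(oxidation)) || any(oxidation < 1L)) {
    stop("oxidation state must be a positive integer", call. = FALSE)
  }
  spin <- match.arg(spin, c("none", "LS", "HS"))
  check_element(metal)
  check_element(ligand)
  spin_tag <- if (spin == "none") "" else paste0(":", spin)
  paste0(metal, oxidation, spin_tag, "-", ligand)
}

#' Parse bond-type keys back into their fields
#'
#' @param key Character vector of keys produced by [bond_type_key()].
#' @return A data.frame with columns `metal`, `oxidation`, `spin`, `ligand`.
#' @export
parse_bond_type <- function(key) {
  m <- regmatches(key, regexec("^([A-Z][a-z]?)([0-9]+)(:(LS|HS))?-([A-Z][a-z]?)$", key))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed bond-type key: ", paste(key[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(
    metal = vapply(m, `[`, "", 2L),
    oxidation = as.integer(vapply(m, `[`, "", 3L)),
    spin = ifelse(vapply(m, `[`, "", 5L) == "", "none", vapply(m, `[`, "", 5L)),
    ligand = vapply(m, `[`, "", 6L),
    stringsAsFactors = FALSE
  )
}

# element symbols accepted anywhere in the package; extraction from
# coordinate files may see more than the six fit ligands
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Sb",
  "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "W", "Re", "Os", "Ir", "Pt",
  "Au", "Hg", "Tl", "Pb", "Bi", "U"
)

check_element <- function(x) {
  bad <- !(x %in% .element_symbols)
  if (any(bad)) {
    stop("not a recognised element symbol: ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Create an empty bond-valence parameter set
#'
#' A parameter set maps bond-type keys to `R0` values (with an uncertainty
#' and a site count), under one global softness parameter `b`. `b` defaults
#' to 0.37 Angstrom, the standard value of the exponential bond
#' length-valence law; it is configurable but never fitted here.
#'
#' @param b Global softness parameter in Angstrom, > 0.
#' @return An object of class `bv_params`.
#' @seealso [set_param()], [get_r0()], [reference_params()]
#' @export
bv_params <- function(b = 0.37) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0) {
    stop("b must be a single positive number", call. = FALSE)
  }
  structure(list(b = b, entries = list()), class = "bv_params")
}

#' Add or replace one parameter entry
#'
#' @param params A `bv_params` object.
#' @param key Bond-type key (see [bond_type_key()]).
#' @param r0 `R0` in Angstrom; must lie in the sanity window (1.0, 3.5).
#' @param uncertainty Nonnegative uncertainty in Angstrom (may be `NA`).
#' @param n_sites Number of sites behind the value (may be `NA`).
#' @param cn_validity Optional integer coordination number outside which the
#'   parameter is known to be unreliable (used for tetrahedral Fe-S).
#' @return The updated `bv_params`.
#' @export
set_param <- function(params, key, r0, uncertainty = NA_real_,
                      n_sites = NA_integer_, cn_validity = NA_integer_) {
  stopifnot(inherits(params, "bv_params"))
  parse_bond_type(key)  # validates
  if (!is.finite(r0) || r0 <= 1.0 || r0 >= 3.5) {
    stop("R0 = ", r0, " outside the sanity window (1.0, 3.5) A for ", key,
         call. = FALSE)
  }
  if (!is.na(uncertainty) && uncertainty < 0) {
    stop("uncertainty must be nonnegative", call. = FALSE)
  }
  params$entries[[key]] <- list(
    r0 = as.numeric(r0),
    uncertainty = as.numeric(uncertainty),
    n_sites = as.integer(n_sites),
    cn_validity = as.integer(cn_validity)
  )
  params
}

#' Look up R0 for a bond-type key
#'
#' Lookup is strict: a missing key is an error naming the key. There is no
#' silent fallback from a spin-resolved key to the unresolved one.
#'
#' @inheritParams set_param
#' @return The `R0` value in Angstrom.
#' @export
get_r0 <- function(params, key) {
  stopifnot(inherits(params, "bv_params"))
  e <- params$entries[[key]]
  if (is.null(e)) {
    stop("missing-parameter: no R0 for bond type '", key, "'", call. = FALSE)
  }
  e$r0
}

#' @export
print.bv_params <- function(x, ...) {
  cat("<bv_params> b =", x$b, "A,", length(x$entries), "bond types\n")
  if (length(x$entries)) print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
as.data.frame.bv_params <- function(x, ...) {
  if (!length(x$entries)) {
    return(data.frame(key = character(), r0 = numeric(),
                      uncertainty = numeric(), n_sites = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    key = names(x$entries),
    r0 = vapply(x$entries, function(e) e$r0, 0),
    uncertainty = vapply(x$entries, function(e) e$uncertainty, 0),
    n_sites = vapply(x$entries, function(e) e$n_sites, 0L),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# Resolve the key used for one contact of a site. Spin enters the key only
# when the parameter set actually declares a split for (metal, ox, ligand);
# a site in a known spin state still uses plain keys for its other ligands.
# A missing resolved key is a hard error (no fallback).
resolve_key <- function(params, metal, oxidation, spin, ligand) {
  if (spin %in% c("LS", "HS")) {
    spin_key <- bond_type_key(metal, oxidation, ligand, spin)
    if (!is.null(params$entries[[spin_key]])) return(spin_key)
    plain <- bond_type_key(metal, oxidation, ligand)
    if (has_split(params, metal, oxidation, ligand)) {
      stop("missing-parameter: no R0 for bond type '", spin_key, "'",
           call. = FALSE)
    }
    return(plain)
  }
  bond_type_key(metal, oxidation, ligand)
}

# does the parameter set declare an LS/HS split for this metal-ligand pair?
has_split <- function(params, metal, oxidation, ligand) {
  any(paste0(metal, oxidation, ":", c("LS", "HS"), "-", ligand) %in%
        names(params$entries))
}
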