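#' Construct a metal coordination site
#'
#' A binding site is one metal center together with its ligand-atom contacts
#' (element and distance per contact), provenance metadata from the source
#' crystal structure, an oxidation-state assignment and an optional spin
#' label. Contacts keep their input order.
#'
#' @param metal Metal element symbol.
#' @param ligands Character vector of ligand element symbols, one per contact.
#' @param distances Numeric vector of metal-ligand distances in Angstrom,
#'   strictly positive, same length as `ligands`.
#' @param oxidation Integer oxidation state, or `NA` when unassigned.
#' @param spin Spin class: `"none"`, `"LS"`, `"HS"` or `"unknown"`.
#' @param entry_id,site_id Identifiers of the source entry and of the site
#'   within it.
#' @param compound_name Compound name as deposited (used by the
#'   oxidation-state name parser).
#' @param r_factor Crystallographic R factor as a fraction (0.075 = 7.5%).
#' @param disordered Whether the structure is disordered.
#' @param metal_carbon Whether the metal has any metal-carbon bond
#'   (organometallic sites are excluded from fitting).
#' @param symmetry Logical vector flagging symmetry-generated contacts.
#' @return An object of class `bv_site`.
#' @examples
#' binding_site("Fe", rep("N", 6), c(2.03, 2.06, 2.15, 2.15, 2.16, 2.2),
#'              oxidation = 2)
#' @export
binding_site <- function(metal, ligands, distances, oxidation = NA,
                         spin = "none", entry_id = "", site_id = "",
                         compound_name = "", r_factor = NA_real_,
                         disordered = FALSE, metal_carbon = FALSE,
                         symmetry = FALSE) {
  check_element(metal)
  if (length(ligands)) check_element(ligands)
  if (length(ligands) != length(distances)) {
    stop("ligands and distances must have equal length", call. = FALSE)
  }
  if (length(distances) && any(!is.finite(distances) | distances <= 0)) {
    stop("distances must be positive and finite", call. = FALSE)
  }
  if (!is.na(oxidation)) {
    if (abs(oxidation - round(oxidation)) > 1e-9 || oxidation < 1) {
      stop("oxidation state must be a positive integer or NA", call. = FALSE)
    }
    oxidation <- as.integer(round(oxidation))
  } else {
    oxidation <- NA_integer_
  }
  spin <- match.arg(spin, c("none", "LS", "HS", "unknown"))
  structure(list(
    entry_id = as.character(entry_id),
    site_id = as.character(site_id),
    metal = metal,
    contacts = data.frame(
      ligand = as.character(ligands),
      distance = as.numeric(distances),
      symmetry = rep_len(as.logical(symmetry), length(ligands)),
      stringsAsFactors = FALSE
    ),
    oxidation = oxidation,
    spin = spin,
    compound_name = as.character(compound_name),
    r_factor = as.numeric(r_factor),
    disordered = isTRUE(disordered),
    metal_carbon = isTRUE(metal_carbon)
  ), class = "bv_site")
}

#' @export
print.bv_site <- function(x, ...) {
  ox <- if (is.na(x$oxidation)) "unassigned" else x$oxidation
  cat(sprintf("<bv_site> %s site %s/%s: %s(%s), %d contacts",
              x$metal, x$entry_id, x$site_id, x$metal, ox,
              nrow(x$contacts)))
  if (x$spin != "none") cat(" [", x$spin, "]", sep = "")
  cat("\n")
  if (nrow(x$contacts)) {
    cat(" ", paste(sprintf("%s:%.2f", x$contacts$ligand, x$contacts$distance),
                   collapse = " "), "\n")
  }
  invisible(x)
}

#' Is a site homoleptic?
#'
#' Homoleptic means every first-sphere ligand atom is the same element.
#'
#' @param site A `bv_site`.
#' @return Logical.
#' @export
is_homoleptic <- function(site) {
  stopifnot(inherits(site, "bv_site"))
  nrow(site$contacts) > 0L && length(unique(site$contacts$ligand)) == 1L
}

#' Coordination number of a site
#' @param site A `bv_site`.
#' @return Integer number of contacts.
#' @export
coordination_number <- function(site) {
  stopifnot(inherits(site, "bv_site"))
  nrow(site$contacts)
}

# per-contact resolved bond-type keys of one site (requires assigned ox)
site_contact_keys <- function(site, params) {
  if (is.na(site$oxidation)) {
    stop("oxidation state unassigned for site ", site$entry_id, "/",
         site$site_id, call. = FALSE)
  }
  vapply(site$contacts$ligand, function(lig) {
    resolve_key(params, site$metal, site$oxidation, site$spin, lig)
  }, "", USE.NAMES = FALSE)
}
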