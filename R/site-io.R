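# Site-table CSV format: one metal->ligand contact per row, with the ten
# documented columns. Rows sharing (entry_id, site_id) form one site.
.site_table_cols <- c("entry_id", "site_id", "metal_element",
                      "compound_name", "r_factor", "disorder_flag",
                      "metal_carbon_flag", "ligand_element",
                      "distance_angstrom", "symmetry_flag")

#' Read a site table
#'
#' Reads the package's contact-per-row CSV format and groups rows into
#' binding sites by `(entry_id, site_id)`, preserving row order within a
#' site. Duplicate contact rows are kept (symmetry-generated contacts are
#' legitimate duplicates by distance). R factors given percent-style
#' (values > 1, e.g. `7.5`) are normalised to fractions with a message.
#'
#' @param path Path to a CSV file with the ten documented columns.
#' @return A list of `bv_site` (oxidation unassigned).
#' @export
read_site_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.site_table_cols, names(df))
  if (length(missing)) {
    stop("site table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$entry_id <- as.character(df$entry_id)
  df$site_id <- as.character(df$site_id)
  if (nrow(df) == 0L) return(list())
  bad <- which(!is.finite(df$distance_angstrom) | df$distance_angstrom <= 0)
  if (length(bad)) {
    stop("malformed distance at data row ", bad[1], " of ", path,
         call. = FALSE)
  }
  pct <- which(!is.na(df$r_factor) & df$r_factor > 1)
  if (length(pct)) {
    message("normalising ", length(pct),
            " percent-style r_factor value(s) to fractions")
    df$r_factor[pct] <- df$r_factor[pct] / 100
  }
  grp <- factor(paste(df$entry_id, df$site_id, sep = "\r"),
                levels = unique(paste(df$entry_id, df$site_id, sep = "\r")))
  lapply(split(df, grp), function(g) {
    binding_site(
      metal = g$metal_element[1],
      ligands = g$ligand_element,
      distances = g$distance_angstrom,
      oxidation = NA,
      entry_id = g$entry_id[1], site_id = g$site_id[1],
      compound_name = g$compound_name[1],
      r_factor = g$r_factor[1],
      disordered = isTRUE(as.logical(g$disorder_flag[1])),
      metal_carbon = isTRUE(as.logical(g$metal_carbon_flag[1])),
      symmetry = as.logical(g$symmetry_flag)
    )
  }) |> unname()
}

#' Write a site table
#'
#' Inverse of [read_site_table()]: one contact per row, bit-stable for
#' fixed input (distances at full precision via `format(..., digits = 17)`).
#'
#' @param sites List of `bv_site`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  rows <- lapply(sites, function(s) {
    n <- nrow(s$contacts)
    if (n == 0L) return(NULL)
    data.frame(
      entry_id = s$entry_id, site_id = s$site_id, metal_element = s$metal,
      compound_name = s$compound_name, r_factor = s$r_factor,
      disorder_flag = s$disordered, metal_carbon_flag = s$metal_carbon,
      ligand_element = s$contacts$ligand,
      distance_angstrom = format(s$contacts$distance, digits = 17),
      symmetry_flag = s$contacts$symmetry,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.site_table_cols)), .site_table_cols))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# cached reference table
.bvfit_cache <- new.env(parent = emptyenv())

reference_table <- function() {
  if (is.null(.bvfit_cache$ref)) {
    path <- system.file("extdata", "reference_r0.csv", package = "bvfit")
    .bvfit_cache$ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .bvfit_cache$ref
}

#' Bundled reference parameter sets
#'
#' Three bundled `R0` tables: `"brese"` - the classical literature
#' reference values for Fe, Na, Mg, K, Ca and Zn bound to N, O, F, S, Cl
#' and Br; `"csd"` - the data-driven values refit from metal-organic
#' crystal structures, including separate low-spin/high-spin Fe-N
#' parameters (Fe(II)-N 1.57/1.76, Fe(III)-N 1.70/1.83) and
#' coordination-number-4-only Fe-S values; `"liu"` - the earlier
#' damped-least-squares iron values.
#'
#' @param set One of `"brese"`, `"csd"`, `"liu"`.
#' @param b Softness parameter attached to the returned set.
#' @return A `bv_params`.
#' @export
reference_params <- function(set = c("brese", "csd", "liu"), b = 0.37) {
  set <- match.arg(set)
  df <- reference_table()
  df <- df[df$set == set, , drop = FALSE]
  p <- bv_params(b = b)
  for (i in seq_len(nrow(df))) {
    key <- bond_type_key(df$metal[i], df$oxidation[i], df$ligand[i],
                         df$spin[i])
    p <- set_param(p, key, df$r0[i], df$uncertainty[i], df$n_sites[i],
                   df$cn_validity[i])
  }
  p
}

#' Bundled typical-distance table
#'
#' Printed typical first-coordination-sphere distances for Na, Mg, K, Ca,
#' Zn (octahedral, tetrahedral for Zn) and Fe (octahedral; tetrahedral for
#' Fe-S), together with the `R0`, the coordination number and the
#' *effective* oxidation state each printed cell corresponds to under
#' `d = R0 - b*log(S/n)`. Two Fe-S cells differ from the recomputed value
#' by 0.01 Angstrom and are flagged `allowlisted`. Note the published Fe
#' rows - including the Fe(III) ones - correspond to `s_effective = 2`
#' (see the package vignette).
#'
#' @return A data.frame with columns `metal`, `oxidation`, `spin`,
#'   `ligand`, `cn`, `s_effective`, `r0`, `distance`, `allowlisted`.
#' @export
typical_distance_table <- function() {
  path <- system.file("extdata", "typical_distances.csv", package = "bvfit")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Extract metal coordination sites from a coordinate file
#'
#' Reads a PDB or mmCIF coordinate file, finds every atom of the requested
#' metal elements, and builds one binding site per metal atom from all
#' non-carbon, non-hydrogen, non-metal atoms within the radius (Euclidean
#' distance in the asymmetric unit; crystallographic symmetry expansion is
#' not performed). Oxidation states are left unassigned; the structure
#' title becomes the compound name.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif` file.
#' @param metal_elements Metal element symbols to extract sites for.
#' @param radius Contact radius in Angstrom (default 4.0).
#' @return A list of `bv_site` (possibly empty, with a message).
#' @export
extract_sites_from_structure <- function(path, metal_elements = "Fe",
                                         radius = 4.0) {
  stopifnot(radius >= 0)
  atoms <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    read_mmcif_atoms(path)
  } else {
    read_pdb_atoms(path)
  }
  check_element(metal_elements)
  non_ligand <- c("C", "H", .common_metals)
  midx <- which(atoms$element %in% metal_elements)
  if (!length(midx)) {
    message("no atoms of ", paste(metal_elements, collapse = "/"),
            " found in ", path)
    return(list())
  }
  sites <- vector("list", length(midx))
  for (k in seq_along(midx)) {
    i <- midx[k]
    dx <- atoms$x - atoms$x[i]
    dy <- atoms$y - atoms$y[i]
    dz <- atoms$z - atoms$z[i]
    d <- sqrt(dx^2 + dy^2 + dz^2)
    sel <- which(d > 0 & d <= radius & !(atoms$element %in% non_ligand))
    sel <- sel[order(d[sel])]
    carbon_bonded <- any(atoms$element == "C" & d > 0 & d <= 2.0)
    sites[[k]] <- binding_site(
      metal = atoms$element[i],
      ligands = atoms$element[sel],
      distances = d[sel],
      oxidation = NA,
      entry_id = tools::file_path_sans_ext(basename(path)),
      site_id = sprintf("%s_%d", atoms$element[i], k),
      compound_name = attr(atoms, "title") %||% "",
      r_factor = NA_real_,
      metal_carbon = carbon_bonded
    )
  }
  sites
}

.common_metals <- c("Li", "Na", "Mg", "Al", "K", "Ca", "Sc", "Ti", "V",
                    "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Rb",
                    "Sr", "Y", "Zr", "Mo", "Ru", "Rh", "Pd", "Ag", "Cd",
                    "Cs", "Ba", "La", "W", "Re", "Os", "Ir", "Pt", "Au",
                    "Hg", "Pb", "U")

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal fixed-width PDB ATOM/HETATM reader; element from columns 77-78,
# falling back to the atom-name field when absent
read_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  title <- trimws(paste(substring(grep("^TITLE", lines, value = TRUE), 11),
                        collapse = " "))
  rec <- grep("^(ATOM|HETATM)", lines, value = TRUE)
  if (!length(rec)) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  elem <- trimws(substring(rec, 77, 78))
  fallback <- !nzchar(elem)
  if (any(fallback)) {
    nm <- trimws(substring(rec[fallback], 13, 16))
    elem[fallback] <- sub("^([A-Za-z]+).*", "\\1", nm)
  }
  elem <- paste0(toupper(substring(elem, 1, 1)), tolower(substring(elem, 2)))
  out <- data.frame(
    element = elem,
    x = as.numeric(substring(rec, 31, 38)),
    y = as.numeric(substring(rec, 39, 46)),
    z = as.numeric(substring(rec, 47, 54)),
    stringsAsFactors = FALSE
  )
  attr(out, "title") <- title
  out
}

# minimal mmCIF atom_site loop reader: type_symbol + Cartesian coordinates
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  for (ls in loop_starts) {
    j <- ls + 1L
    fields <- character(0)
    while (j <= length(lines) && grepl("^\\s*_", lines[j])) {
      fields <- c(fields, trimws(lines[j]))
      j <- j + 1L
    }
    if (!any(grepl("^_atom_site\\.", fields))) next
    fields <- sub("^_atom_site\\.", "", fields)
    rows <- list()
    while (j <= length(lines)) {
      ln <- trimws(lines[j])
      if (!nzchar(ln) || grepl("^(loop_|_|#)", ln)) break
      rows[[length(rows) + 1L]] <- scan(text = ln, what = "character",
                                        quiet = TRUE)
      j <- j + 1L
    }
    m <- do.call(rbind, rows)
    colnames(m) <- fields[seq_len(ncol(m))]
    need <- c("type_symbol", "Cartn_x", "Cartn_y", "Cartn_z")
    if (!all(need %in% colnames(m))) {
      stop("mmCIF atom_site loop lacks ", paste(setdiff(need, colnames(m)),
                                                collapse = ", "),
           call. = FALSE)
    }
    elem <- m[, "type_symbol"]
    elem <- paste0(toupper(substring(elem, 1, 1)),
                   tolower(substring(elem, 2)))
    title_ln <- grep("^_struct\\.title", lines, value = TRUE)
    title <- if (length(title_ln)) {
      trimws(gsub("^_struct\\.title\\s*|['\"]", "", title_ln[1]))
    } else ""
    out <- data.frame(
      element = elem,
      x = as.numeric(m[, "Cartn_x"]),
      y = as.numeric(m[, "Cartn_y"]),
      z = as.numeric(m[, "Cartn_z"]),
      stringsAsFactors = FALSE
    )
    attr(out, "title") <- title
    return(out)
  }
  stop("no atom_site loop found in ", path, call. = FALSE)
}

#' Write a parameter table
#'
#' Emits a CSV shaped like the published summary tables: one row per bond
#' type with the homoleptic mean (sd) and count, the optimised `R0` with
#' its uncertainty and total site count, the literature value, and a
#' significance flag set when `|fitted - literature| > 0.1` Angstrom (the
#' conventional threshold below which parameter differences between data
#' sets are not considered meaningful).
#'
#' @param fit A `bv_fit` or `bv_params`.
#' @param path Output CSV path.
#' @param homoleptic Optional [homoleptic_summary()] data.frame.
#' @param literature Optional `bv_params` with literature values.
#' @return The written data.frame, invisibly.
#' @export
write_parameter_table <- function(fit, path, homoleptic = NULL,
                                  literature = NULL) {
  params <- if (inherits(fit, "bv_fit")) fit$params else fit
  stopifnot(inherits(params, "bv_params"))
  df <- as.data.frame(params)
  names(df)[names(df) == "r0"] <- "r0_fitted"
  names(df)[names(df) == "n_sites"] <- "n_total"
  df$homoleptic_mean <- rep(NA_real_, nrow(df))
  df$homoleptic_sd <- rep(NA_real_, nrow(df))
  df$n_homoleptic <- rep(NA_integer_, nrow(df))
  if (!is.null(homoleptic) && nrow(homoleptic)) {
    m <- match(df$key, homoleptic$key)
    df$homoleptic_mean <- homoleptic$mean_r0[m]
    df$homoleptic_sd <- homoleptic$sd_r0[m]
    df$n_homoleptic <- homoleptic$n[m]
  }
  df$r0_literature <- rep(NA_real_, nrow(df))
  if (!is.null(literature)) {
    df$r0_literature <- vapply(df$key, function(k) {
      info <- parse_bond_type(k)
      # spin-resolved fits compare against the single literature value
      plain <- bond_type_key(info$metal, info$oxidation, info$ligand)
      e <- literature$entries[[k]] %||% literature$entries[[plain]]
      if (is.null(e)) NA_real_ else e$r0
    }, 0)
  }
  df$significant <- !is.na(df$r0_literature) &
    abs(df$r0_fitted - df$r0_literature) > 0.1
  df <- df[, c("key", "homoleptic_mean", "homoleptic_sd", "n_homoleptic",
               "r0_fitted", "uncertainty", "n_total", "r0_literature",
               "significant")]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(df)
}

#' Read a parameter table written by [write_parameter_table()]
#'
#' @param path CSV path.
#' @param b Softness parameter for the reconstructed set.
#' @return A `bv_params` built from the `r0_fitted` column.
#' @export
read_parameter_table <- function(path, b = 0.37) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  p <- bv_params(b = b)
  for (i in seq_len(nrow(df))) {
    p <- set_param(p, df$key[i], df$r0_fitted[i],
                   df$uncertainty[i], df$n_total[i])
  }
  p
}
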