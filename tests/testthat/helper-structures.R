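# synthetic coordinate-file fixtures built in code (no binary data)

pdb_atom_line <- function(serial, name, res, resseq, x, y, z, element,
                          record = "ATOM") {
  sprintf("%-6s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, res, resseq, x, y, z, 1.00, 10.00, element)
}

# Fe at the origin with ligand atoms at the given distances along the six
# octahedral axes (recycled beyond six), plus optional extra atoms
write_octahedral_pdb <- function(path, distances, elements = "N",
                                 extra = character(0),
                                 title = "SYNTHETIC IRON(III) TEST SITE") {
  axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  elements <- rep_len(elements, length(distances))
  lines <- c(paste0("TITLE     ", title),
             pdb_atom_line(1, "FE", "FE", 1, 0, 0, 0, "FE", "HETATM"))
  for (i in seq_along(distances)) {
    ax <- axes[((i - 1) %% 6) + 1, ] * distances[i]
    lines <- c(lines, pdb_atom_line(1 + i, paste0(elements[i], i), "LIG",
                                    1 + i, ax[1], ax[2], ax[3],
                                    toupper(elements[i]), "HETATM"))
  }
  for (e in extra) lines <- c(lines, e)
  writeLines(c(lines, "END"), path)
  path
}

write_octahedral_cif <- function(path, distances, elements = "N",
                                 title = "synthetic test site") {
  axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  elements <- rep_len(elements, length(distances))
  rows <- sprintf("HETATM 1 Fe %.3f %.3f %.3f", 0, 0, 0)
  for (i in seq_along(distances)) {
    ax <- axes[((i - 1) %% 6) + 1, ] * distances[i]
    rows <- c(rows, sprintf("HETATM %d %s %.3f %.3f %.3f",
                            1 + i, toupper(elements[i]),
                            ax[1], ax[2], ax[3]))
  }
  writeLines(c(
    "data_synthetic",
    sprintf("_struct.title '%s'", title),
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    rows
  ), path)
  path
}
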