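# Hand-constructed PDB text fixtures exercising parser corner cases.

pdb_atom_line <- function(record = "ATOM", serial, name, resname, chain,
                          resnum, x, y, z, occ = 1.0, altloc = " ",
                          element = NULL, icode = " ") {
  if (is.null(element)) {
    element <- substr(gsub("[^A-Za-z]", "", name), 1, 1)
  }
  name_field <- if (nchar(element) == 2) sprintf("%-4s", name)
    else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%s%-3s %1s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_field, altloc, resname, chain, resnum, icode,
          x, y, z, occ, 0, element)
}

pdb_seqres_lines <- function(chain, name3_vec) {
  n <- length(name3_vec)
  out <- character(0); row <- 1
  for (start in seq(1, n, by = 13)) {
    toks <- name3_vec[start:min(n, start + 12)]
    out <- c(out, sprintf("SEQRES %3d %1s %4d  %s", row, chain, n,
                          paste(sprintf("%-3s", toks), collapse = " ")))
    row <- row + 1
  }
  out
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# minimal 30-residue chain fixture: SEQRES of 30 ALA, CA-only coordinates for
# a subset of residues, optional extras appended
simple_chain_fixture <- function(observed = 1:25, chain = "A",
                                 extra_lines = character(0),
                                 header_id = "TST1") {
  lines <- c(
    sprintf("HEADER    TEST PROTEIN                            01-JAN-20   %s", header_id),
    pdb_seqres_lines(chain, rep("ALA", 30))
  )
  serial <- 1
  for (i in observed) {
    lines <- c(lines,
               pdb_atom_line("ATOM", serial, "N", "ALA", chain, i,
                             i * 3.8, 0, 0),
               pdb_atom_line("ATOM", serial + 1, "CA", "ALA", chain, i,
                             i * 3.8 + 1.4, 0.5, 0),
               pdb_atom_line("ATOM", serial + 2, "C", "ALA", chain, i,
                             i * 3.8 + 2.4, 1.2, 0.3),
               pdb_atom_line("ATOM", serial + 3, "O", "ALA", chain, i,
                             i * 3.8 + 2.9, 2.2, 0.6))
    serial <- serial + 4
  }
  write_pdb_text(c(lines, extra_lines))
}

gnp_het_lines <- function(serial0 = 900, chain = "B", n_atoms = 32,
                          origin = c(50, 50, 50)) {
  vapply(seq_len(n_atoms), function(k) {
    pdb_atom_line("HETATM", serial0 + k, paste0("C", k), "GNP", chain, 1,
                  origin[1] + k * 0.5, origin[2], origin[3], element = "C")
  }, character(1))
}
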