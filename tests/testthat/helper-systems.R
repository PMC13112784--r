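# Small PDB text builders used by the structure-io tests.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element, icode = "", altloc = " ", het = FALSE) {
  sprintf("%-6s%5d %-4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          if (het) "HETATM" else "ATOM", serial,
          if (nchar(name) < 4) paste0(" ", name) else name,
          altloc, resname, chain, resno,
          if (icode == "") " " else icode, x, y, z, element)
}

write_toy_pdb <- function(path) {
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0.00, 0.00, 0.0, "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.46, 0.00, 0.0, "C"),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.00, 1.42, 0.0, "C"),
    pdb_atom_line(4, "O", "ALA", "A", 1, 1.40, 2.49, 0.0, "O"),
    pdb_atom_line(5, "CB", "ALA", "A", 1, 2.00, -0.80, 1.2, "C"),
    pdb_atom_line(6, "N", "GLY", "A", 2, 3.33, 1.54, 0.0, "N"),
    pdb_atom_line(7, "CA", "GLY", "A", 2, 4.00, 2.80, 0.0, "C"),
    pdb_atom_line(8, "C", "GLY", "A", 2, 5.50, 2.60, 0.0, "C"),
    pdb_atom_line(9, "O", "GLY", "A", 2, 6.00, 1.50, 0.0, "O"),
    "TER",
    pdb_atom_line(10, "O", "HOH", "W", 301, 8.0, 8.0, 8.0, "O", het = TRUE),
    "END")
  writeLines(lines, path)
  path
}
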