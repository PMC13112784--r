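test_that("PDB parsing groups residues, flags waters, rejects bad altLocs", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path)
  sys <- read_pdb(path)
  expect_equal(nrow(sys$residues), 3)
  expect_equal(sum(sys$residues$is_water), 1)
  expect_equal(sys$residues$reskey, c("A:1", "A:2", "W:301"))

  # residue represented only by a non-'A' altLoc is an error naming it
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C",
                             altloc = "B"), "END"), bad)
  expect_error(read_pdb(bad), "A:1")

  # duplicate atom name within a residue
  dup <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
               pdb_atom_line(2, "CA", "ALA", "A", 1, 1, 0, 0, "C"),
               "END"), dup)
  expect_error(read_pdb(dup), "duplicate atom name")
})

test_that("insertion codes survive a PDB -> MOL2 round trip", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "N", "GLY", "H", 52, 0.0, 0, 0, "N"),
    pdb_atom_line(2, "CA", "GLY", "H", 52, 1.46, 0, 0, "C"),
    pdb_atom_line(3, "C", "GLY", "H", 52, 2.0, 1.42, 0, "C"),
    pdb_atom_line(4, "O", "GLY", "H", 52, 1.4, 2.49, 0, "O"),
    pdb_atom_line(5, "N", "GLY", "H", 52, 3.33, 1.54, 0, "N", icode = "A"),
    pdb_atom_line(6, "CA", "GLY", "H", 52, 4.0, 2.8, 0, "C", icode = "A"),
    pdb_atom_line(7, "C", "GLY", "H", 52, 5.5, 2.6, 0, "C", icode = "A"),
    pdb_atom_line(8, "O", "GLY", "H", 52, 6.0, 1.5, 0, "O", icode = "A"),
    "END"), path)
  sys <- read_pdb(path)
  expect_setequal(sys$residues$reskey, c("H:52", "H:52A"))
  typed <- apply_typing(sys)
  m2 <- withr::local_tempfile(fileext = ".mol2")
  write_mol2(typed, m2)
  back <- read_mol2(m2)
  expect_setequal(back$residues$reskey, c("H:52", "H:52A"))
})

test_that("dictionary typing assigns SYBYL types, charges and bonds", {
  dict <- default_typing_dictionary()
  expect_equal(dictionary_lookup(dict, "ALA", "CB")$sybyl, "C.3")
  expect_equal(dictionary_lookup(dict, "HOH", "O")$sybyl, "O.3")
  # water template bonds two hydrogens to O
  wb <- dict$bonds[dict$bonds$resname == "HOH", ]
  expect_setequal(wb$b, c("H1", "H2"))
  # disulfide variant has no thiol hydrogen
  expect_null(dictionary_lookup(dict, "CYX", "HG"))
  expect_equal(dictionary_lookup(dict, "CYX", "SG")$sybyl, "S.3")

  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path)
  typed <- apply_typing(read_pdb(path))
  expect_false(anyNA(typed$atoms$sybyl))
  expect_equal(sum(typed$bonds$type == "am"), 1)   # one peptide bond
  # unknown pair reported by name
  bad <- read_pdb(path)
  bad$atoms$name[5] <- "XX9"
  expect_error(apply_typing(bad), "ALA, XX9")
})

test_that("dictionary covers all canonical residues in both dialects", {
  for (dia in c("pdb2pqr", "gmx")) {
    dict <- default_typing_dictionary(dia)
    resn <- unique(dict$entries$resname)
    expect_true(all(c("ALA", "ARG", "ASN", "ASP", "CYS", "CYX", "GLN",
                      "GLU", "GLY", "HIS", "ILE", "LEU", "LYS", "MET",
                      "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
                      "HOH", "WAT") %in% resn))
    # every heavy entry's SYBYL leading token matches its element
    e <- dict$entries
    expect_true(all(sub("\\..*$", "", e$sybyl) == e$element))
    # GLY alpha hydrogens follow the dialect numbering
    ha <- e$atom[e$resname == "GLY" & grepl("^HA", e$atom)]
    expect_setequal(ha, if (dia == "pdb2pqr") c("HA2", "HA3")
                    else c("HA1", "HA2"))
  }
  # text format round trip
  dict <- default_typing_dictionary()
  f <- withr::local_tempfile(fileext = ".txt")
  write_typing_dictionary(dict, f)
  back <- read_typing_dictionary(f)
  expect_equal(back$entries$sybyl, dict$entries$sybyl)
  expect_equal(back$entries$charge, dict$entries$charge, tolerance = 1e-4)
  expect_equal(nrow(back$bonds), nrow(dict$bonds))
})

test_that("declared disulfides get an SG-SG bond with CYX typing", {
  mk <- function(serial0, chain, resno, x0) c(
    pdb_atom_line(serial0, "N", "CYS", chain, resno, x0, 0, 0, "N"),
    pdb_atom_line(serial0 + 1, "CA", "CYS", chain, resno, x0 + 1.5, 0, 0, "C"),
    pdb_atom_line(serial0 + 2, "C", "CYS", chain, resno, x0 + 2, 1.4, 0, "C"),
    pdb_atom_line(serial0 + 3, "O", "CYS", chain, resno, x0 + 1.4, 2.5, 0, "O"),
    pdb_atom_line(serial0 + 4, "CB", "CYS", chain, resno, x0 + 2, -0.8, 1.2, "C"),
    pdb_atom_line(serial0 + 5, "SG", "CYS", chain, resno, x0 + 2, -0.8, 2.9, "S"))
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(mk(1, "A", 1, 0), "TER", mk(7, "B", 1, 1.0), "END"), path)
  typed <- apply_typing(read_pdb(path),
                        disulfides = list(c("A:1", "B:1")))
  sg <- typed$atoms$serial[typed$atoms$name == "SG"]
  ss <- typed$bonds[(typed$bonds$a %in% sg) & (typed$bonds$b %in% sg), ]
  expect_equal(nrow(ss), 1)
  expect_equal(ss$type, "1")
})

test_that("MOL2 writing is typed-only and reading demands charges", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path)
  untyped <- read_pdb(path)
  expect_error(write_mol2(untyped, withr::local_tempfile()), "not fully typed")

  nochg <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "x", "1 0 1", "SMALL", "NO_CHARGES", "",
               "@<TRIPOS>ATOM", "1 CA 0.0 0.0 0.0 C.3 1 ALA1"), nochg)
  expect_error(read_mol2(nochg), "charge")
  noatom <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "x"), noatom)
  expect_error(read_mol2(noatom), "ATOM section")
})

test_that("MOL2 round trip is lossless on types, charges, bonds, coords", {
  toy <- make_toy_complex()$system
  f <- withr::local_tempfile(fileext = ".mol2")
  write_mol2(toy, f)
  back <- read_mol2(f)
  expect_equal(back$atoms$sybyl, toy$atoms$sybyl)
  expect_equal(back$atoms$charge, toy$atoms$charge, tolerance = 1e-4)
  expect_equal(back$atoms$x, toy$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$z, toy$atoms$z, tolerance = 1e-3)
  key <- function(s) sort(paste(pmin(s$bonds$a, s$bonds$b),
                                pmax(s$bonds$a, s$bonds$b), s$bonds$type))
  expect_equal(key(back), key(toy))
  # an aromatic ring written as ar bonds is perceived again on re-read
  rings <- find_rings(back)
  expect_true(any(vapply(rings, function(r) r$reskey == "A:12", logical(1))))
})

test_that("partner classes partition residues with waters as solvent", {
  toy <- make_toy_complex()$system
  cls <- toy$residues$class
  expect_false(anyNA(cls))
  expect_equal(sum(cls == "M"), 1)
  expect_equal(sum(cls == "S"), 2)
  expect_true(all(cls %in% c("M", "Ab", "Ag", "S")))

  # DPM: two listed residues both class M
  sys2 <- assign_partner_classes(toy,
    list(targets = list("H:57", "A:10"), chains = c(H = "Ab", A = "Ab",
                                                    B = "Ag")))
  expect_equal(sum(sys2$residues$class == "M"), 2)
  # errors: empty target list, absent residue, unmapped chain
  expect_error(assign_partner_classes(toy, list(targets = list(),
                                                chains = c(H = "Ab"))),
               "empty target")
  expect_error(assign_partner_classes(toy,
    list(targets = list("H:99"), chains = c(H = "Ab"))), "H:99")
  expect_error(assign_partner_classes(toy,
    list(targets = list("H:57"), chains = c(H = "Ab"))), "unmapped")
})

test_that("hydrogen fallback types unknown hydrogens by attachment", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.46, 0, 0, "C"),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.0, 1.42, 0, "C"),
    pdb_atom_line(4, "O", "ALA", "A", 1, 1.4, 2.49, 0, "O"),
    pdb_atom_line(5, "CB", "ALA", "A", 1, 2.0, -0.8, 1.2, "C"),
    pdb_atom_line(6, "HXT", "ALA", "A", 1, 2.4, -1.6, 0.6, "H"),
    "END"), path)
  expect_error(apply_typing(read_pdb(path)), "HXT")
  typed <- apply_typing(read_pdb(path), hydrogen_fallback = TRUE)
  h <- typed$atoms[typed$atoms$name == "HXT", ]
  expect_equal(h$sybyl, "H")
  cb <- typed$atoms$serial[typed$atoms$name == "CB"]
  expect_true(any((typed$bonds$a == cb & typed$bonds$b == h$serial) |
                  (typed$bonds$b == cb & typed$bonds$a == h$serial)))
})
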