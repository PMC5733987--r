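pdb_line <- function(rec = "ATOM", serial = 1, name = "CA", altloc = " ",
                     resname = "GLY", chain = "A", resseq = 1,
                     x = 0, y = 0, z = 0, occ = 1, element = "C") {
  sprintf("%-6s%5d %s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial,
          if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name),
          altloc, resname, chain, resseq, x, y, z, occ, 0, element)
}

test_that("toy PDB file parses into atoms/residues/chains", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(serial = 1, name = "N", element = "N"),
               pdb_line(serial = 2, name = "CA", x = 1.458),
               pdb_line(serial = 3, name = "C", x = 2, y = 1.4),
               "END"), f)
  st <- parse_pdb(f)
  expect_equal(nrow(st$atoms), 3L)
  expect_equal(unique(st$atoms$chain), "A")
  expect_equal(unique(st$atoms$resseq), 1L)
  expect_equal(st$atoms$x[2], 1.458)
})

test_that("altloc resolution keeps the highest occupancy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(serial = 1, altloc = "A", occ = 0.6, x = 1),
               pdb_line(serial = 2, altloc = "B", occ = 0.4, x = 2),
               "END"), f)
  st <- parse_pdb(f)
  expect_equal(nrow(st$atoms), 1L)
  expect_equal(st$atoms$x, 1)
  # occupancy tie resolved toward altloc A
  writeLines(c(pdb_line(serial = 1, altloc = "B", occ = 0.5, x = 2),
               pdb_line(serial = 2, altloc = "A", occ = 0.5, x = 1),
               "END"), f)
  expect_equal(parse_pdb(f)$atoms$x, 1)
})

test_that("synthetic 100-residue structure round-trips to 3 decimals", {
  atoms <- withr::with_seed(99, do.call(rbind, lapply(1:100, function(i) {
    protchar:::atom_row(i, "CA", "ALA", "A", i,
                        round(runif(3, -80, 400), 3), "C")
  })))
  st <- protchar:::as_structure(atoms)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(st, f)
  back <- parse_pdb(f)
  expect_equal(back$atoms$x, st$atoms$x, tolerance = 1e-8)
  expect_equal(back$atoms$y, st$atoms$y, tolerance = 1e-8)
  expect_equal(back$atoms$z, st$atoms$z, tolerance = 1e-8)
  expect_equal(back$atoms$resseq, st$atoms$resseq)
  expect_equal(back$atoms$name, st$atoms$name)
})

test_that("malformed coordinates and empty files error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  l <- pdb_line()
  substr(l, 31, 38) <- "  xx.yyy"
  writeLines(l, f)
  expect_error(parse_pdb(f), "malformed|non-finite")
  writeLines(c("HEADER", "END"), f)
  expect_error(parse_pdb(f), "no ATOM")
  expect_error(parse_pdb(file.path(tempdir(), "absent.pdb")), "not found")
})

test_that("HETATM, water flags and MODEL blocks", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1",
               pdb_line(x = 1),
               pdb_line(rec = "HETATM", serial = 2, name = "O", x = 5,
                        resname = "HOH", resseq = 2, element = "O"),
               pdb_line(rec = "HETATM", serial = 3, name = "C1", x = 7,
                        resname = "NAG", resseq = 3),
               "ENDMDL",
               "MODEL     2",
               pdb_line(x = 99),
               "ENDMDL"), f)
  st <- parse_pdb(f)
  expect_equal(nrow(st$atoms), 3L)  # first model only
  expect_equal(st$atoms$x[1], 1)
  expect_equal(st$atoms$het, c(FALSE, TRUE, TRUE))
  expect_equal(st$atoms$water, c(FALSE, TRUE, FALSE))
})

test_that("select_atoms filters exactly and preserves file order", {
  st <- build_toy_structure("lys_acid_pair", list(d = 5))
  sel <- select_atoms(st, resname = "LYS", atom_name = "NZ")
  expect_equal(nrow(sel), 1L)
  expect_equal(select_atoms(st, chain = "Z"),
               st$atoms[0, ], ignore_attr = TRUE)
  # random selections vs exhaustive filter oracle
  a <- st$atoms
  for (rn in unique(a$resname)) {
    got <- select_atoms(st, resname = rn)
    want <- a[a$resname == rn, , drop = FALSE]
    expect_equal(got$serial, want$serial)
  }
})
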