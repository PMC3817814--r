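test_that("fixtures round-trip through write and parse", {
  for (kind in c("methane", "ethane", "peptide_backbone")) {
    m <- make_molecule(kind)
    m2 <- parse_pdb(write_pdb(m))
    expect_identical(nrow(m2$atoms), nrow(m$atoms))
    cols <- c("name", "resname", "resseq", "element")
    expect_identical(m2$atoms[cols], m$atoms[cols])
    expect_equal(m2$atoms$x, m$atoms$x, tolerance = 1e-3)
    expect_equal(m2$atoms$y, m$atoms$y, tolerance = 1e-3)
    expect_equal(m2$atoms$z, m$atoms$z, tolerance = 1e-3)
    expect_null(m2$crystal)
  }
})

test_that("parsed coordinates agree with an independent PDB reader", {
  expect_true(requireNamespace("bio3d", quietly = TRUE))
  f <- write_fixture(write_pdb(make_molecule("ethane")))
  ours <- read_pdb(f)
  ref <- bio3d::read.pdb(f)
  expect_equal(ours$atoms$x, ref$atom$x, tolerance = 1e-6)
  expect_equal(ours$atoms$y, ref$atom$y, tolerance = 1e-6)
  expect_equal(ours$atoms$z, ref$atom$z, tolerance = 1e-6)
  expect_equal(trimws(ours$atoms$name), trimws(ref$atom$elety))
})

test_that("BIOMT blocks parse into joined transform records", {
  hdr <- c("REMARK 350 BIOMOLECULE: 1",
           "REMARK 350 APPLY THE FOLLOWING TO CHAINS: A",
           "REMARK 350   BIOMT1   1  1.000000  0.000000  0.000000        0.00000",
           "REMARK 350   BIOMT2   1  0.000000  1.000000  0.000000        0.00000",
           "REMARK 350   BIOMT3   1  0.000000  0.000000  1.000000        0.00000",
           "REMARK 350   BIOMT1   2 -1.000000  0.000000  0.000000       15.00000",
           "REMARK 350   BIOMT2   2  0.000000 -1.000000  0.000000        0.00000",
           "REMARK 350   BIOMT3   2  0.000000  0.000000  1.000000        0.00000")
  m <- parse_pdb(c(hdr, write_pdb(make_molecule("ethane"))))
  expect_identical(length(m$biomt), 1L)
  expect_identical(length(m$biomt[["1"]]$transforms), 2L)
  expect_identical(m$biomt[["1"]]$chains, "A")
  tr2 <- m$biomt[["1"]]$transforms[[2]]
  expect_equal(tr2$rotation, diag(c(-1, -1, 1)))
  expect_equal(tr2$translation, c(15, 0, 0))
  # every well-formed record came from exactly 3 rows
  expect_true(all(vapply(m$biomt[["1"]]$transforms,
                         function(t) all(dim(t$rotation) == c(3, 3)), TRUE)))
})

test_that("toy crystal headers carry SMTRY operators of the space group", {
  m <- parse_pdb(make_toy_crystal("P 21 21 21", "rod", 20, 20, 20))
  expect_identical(length(m$smtry), 4L)
  expect_identical(m$crystal$space_group_symbol, "P 21 21 21")
  m2 <- parse_pdb(make_toy_crystal("P 1 21 1", "rod", 20, 20, 20))
  expect_identical(length(m2$smtry), 2L)
})

test_that("altloc duplicates resolve to the highest-occupancy conformer", {
  base <- write_pdb(make_molecule("methane"))
  atom_line <- base[grepl("^ATOM", base)][1]
  a50 <- atom_line
  substr(a50, 17, 17) <- "A"; substr(a50, 55, 60) <- "  0.50"
  b50 <- atom_line
  substr(b50, 17, 17) <- "B"; substr(b50, 55, 60) <- "  0.70"
  substr(b50, 31, 38) <- "   9.000"
  m <- parse_pdb(c(a50, b50, base[grepl("^ATOM", base)][-1]))
  expect_identical(nrow(m$atoms), 5L)
  expect_equal(m$atoms$x[m$atoms$name == "C1"], 9.0)  # occupancy 0.70 wins
})

test_that("malformed CRYST1 drops the crystal with a warning", {
  lines <- c("CRYST1   -5.000   10.000   10.000  90.00  90.00  90.00 P 1           1",
             write_pdb(make_molecule("methane")))
  expect_warning(m <- parse_pdb(lines), "CRYST1")
  expect_null(m$crystal)
})

test_that("waters are dropped by default but kept on request", {
  wat <- "HETATM    1  O   HOH W   1      30.000  30.000  30.000  1.00  0.00           O"
  lines <- c(write_pdb(make_molecule("methane"))[1:5], wat, "END")
  expect_identical(nrow(parse_pdb(lines)$atoms), 5L)
  expect_identical(nrow(parse_pdb(lines, remove_waters = FALSE)$atoms), 6L)
})

test_that("atom-serial capacity is enforced per overflow policy", {
  big <- make_molecule("methane")
  big$atoms <- big$atoms[rep(1:5, 20001), ]   # 100,005 atoms
  n <- nrow(big$atoms)
  ## unique (chain, resseq, name) identities so no altloc collapsing occurs
  big$atoms$resseq <- ((seq_len(n) - 1L) %/% 5L) %% 9999L + 1L
  big$atoms$chain_id <- LETTERS[((seq_len(n) - 1L) %/% (5L * 9999L)) %% 26L + 1L]
  big$atoms$serial <- seq_len(n)
  rownames(big$atoms) <- NULL
  expect_error(write_pdb(big, overflow_policy = "error"), "99,999")
  expect_warning(write_pdb(big, overflow_policy = "wrap"), "wrapped")
  hy <- write_pdb(big, overflow_policy = "hybrid")
  reparsed <- parse_pdb(hy)
  expect_identical(nrow(reparsed$atoms), 100005L)
  expect_equal(reparsed$atoms$serial[100005], 100005)
})

test_that("chain relabeling cycle yields unique labels for 40 chains", {
  m <- make_molecule("methane")
  at <- do.call(rbind, lapply(1:40, function(k) {
    a <- m$atoms; a$chain_id <- sprintf("c%02d", k); a
  }))
  at$serial <- seq_len(nrow(at)); rownames(at) <- NULL
  m$atoms <- at
  out <- write_pdb(m)
  map <- attr(out, "chain_map")
  expect_identical(length(map), 40L)
  expect_identical(anyDuplicated(map), 0L)
  expect_true(all(nchar(map) == 1))
})

test_that("no-atoms input is a hard error", {
  expect_error(parse_pdb(c("REMARK 1", "END")), "ATOM")
})

test_that("unit labels survive a write/parse round trip", {
  m <- parse_pdb(make_toy_crystal("P 1 21 1", "rod", 20, 20, 20))
  cell <- build_unit_cell(m)
  back <- parse_pdb(write_pdb(cell))
  expect_identical(back$atoms$unit_label, cell$atoms$unit_label)
})
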