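test_that("covalent bonds are inferred with correct rotatability classes", {
  e <- make_molecule("ethane")
  b <- infer_covalent_bonds(e)
  expect_identical(nrow(b), 7L)
  rot <- b[b$order_class == "single_rotatable", ]
  expect_identical(nrow(rot), 1L)          # only the central C-C
  els <- e$atoms$element
  expect_identical(els[rot$i], "C"); expect_identical(els[rot$j], "C")

  # peptide C-N bonds are locked
  p <- make_molecule("peptide_backbone", 2)
  bp <- infer_covalent_bonds(p)
  nm <- p$atoms$name
  cn <- bp[(nm[bp$i] == "C" & nm[bp$j] == "N") |
             (nm[bp$i] == "N" & nm[bp$j] == "C"), ]
  expect_identical(nrow(cn), 2L)
  expect_true(all(cn$order_class == "locked"))

  # atoms far apart do not bond
  two <- make_molecule("methane")
  far <- two$atoms; far$x <- far$x + 10
  far$resseq <- 2L; far$serial <- far$serial + 5L
  two$atoms <- rbind(two$atoms, far)
  b2 <- infer_covalent_bonds(two)
  expect_identical(nrow(b2), 8L)           # 4 C-H per methane, no cross bonds
})

test_that("ring bonds are locked so cyclopropane is one body", {
  ring <- parse_pdb(make_toy_crystal("P 1", "ring", 30, 30, 30))
  mm <- build_mechanical_model(ring)
  expect_identical(length(mm$bodies), 1L)
  expect_identical(nrow(mm$hinges), 0L)
})

test_that("bodies and hinges follow the body-bar-hinge conventions", {
  mm_met <- partition_bodies(make_molecule("methane"))
  expect_identical(length(mm_met$bodies), 1L)
  expect_identical(nrow(mm_met$hinges), 0L)

  mm_eth <- partition_bodies(make_molecule("ethane"))
  expect_identical(length(mm_eth$bodies), 2L)
  expect_identical(nrow(mm_eth$hinges), 1L)
  # hinge atoms belong to both bodies and are the only shared atoms
  shared <- intersect(mm_eth$bodies[[1]], mm_eth$bodies[[2]])
  expect_identical(sort(shared), sort(c(mm_eth$hinges$i, mm_eth$hinges$j)))
  expect_identical(length(shared), 2L)
  # bodies cover all atoms
  expect_identical(sort(unique(unlist(mm_eth$bodies))),
                   seq_len(nrow(mm_eth$atoms)))

  mm_pep <- partition_bodies(make_molecule("peptide_backbone", 2))
  expect_identical(length(mm_pep$bodies), 3L)
  expect_identical(nrow(mm_pep$hinges), 2L)
})

test_that("ideal hydrogen-bond geometry is detected with Mayo energy", {
  ## linear N-H...O=C, H...A = 2.0 A
  geo <- rbind(
    data.frame(name = "N", element = "N", x = 0, y = 0, z = 0,
               resname = "DON", resseq = 1L),
    data.frame(name = "H", element = "H", x = 1.01, y = 0, z = 0,
               resname = "DON", resseq = 1L),
    data.frame(name = "O", element = "O", x = 3.01, y = 0, z = 0,
               resname = "ACC", resseq = 2L),
    data.frame(name = "C", element = "C", x = 4.24, y = 0, z = 0,
               resname = "ACC", resseq = 2L))
  m <- rigidcryst:::structure_from_geom(geo)
  hb <- detect_hbonds(m)
  expect_identical(nrow(hb), 1L)
  expect_lt(hb$energy, -1.0)
  expect_equal(hb$energy, mayo_energy(3.01, pi), tolerance = 1e-9)
  expect_false(hb$inter_unit)

  ## same donor-acceptor pair at an 80-degree D-H-A angle is rejected
  geo80 <- geo
  ang <- 80 * pi / 180
  geo80$x[3] <- 1.01 + 2.0 * cos(pi - ang)
  geo80$y[3] <- 2.0 * sin(pi - ang)
  geo80$x[4] <- geo80$x[3] + 1.23
  m80 <- rigidcryst:::structure_from_geom(geo80)
  expect_identical(nrow(detect_hbonds(m80)), 0L)
})

test_that("a structure without polar hydrogens warns and yields no hbonds", {
  geo <- rbind(
    data.frame(name = "N", element = "N", x = 0, y = 0, z = 0,
               resname = "DON", resseq = 1L),
    data.frame(name = "C", element = "C", x = 1.4, y = 0, z = 0,
               resname = "DON", resseq = 1L),
    data.frame(name = "O", element = "O", x = 3.0, y = 0, z = 0,
               resname = "ACC", resseq = 2L))
  m <- rigidcryst:::structure_from_geom(geo)
  expect_warning(hb <- detect_hbonds(m), "protonated")
  expect_identical(nrow(hb), 0L)
})

test_that("inter-unit hydrogen bonds are flagged and counted per interface", {
  m <- parse_pdb(make_toy_crystal("P 1", "rod", 5.64, 20, 20))
  sc <- build_supercell(build_unit_cell(m), 2, 1, 1)
  mm <- build_mechanical_model(sc)
  expect_identical(nrow(mm$hbonds), 1L)
  expect_true(all(mm$hbonds$inter_unit))
  iface <- count_interface_interactions(mm)
  expect_identical(nrow(iface), 1L)
  expect_identical(iface$hbonds, 1L)
  # single-unit model: empty interface map
  mm1 <- build_mechanical_model(m)
  expect_identical(nrow(count_interface_interactions(mm1)), 0L)
})

test_that("hydrophobic contacts respect elements, distance and tolerance", {
  two_methane <- function(sep) {
    m <- make_molecule("methane")
    far <- m$atoms
    far$x <- far$x + sep; far$resseq <- 2L
    m$atoms <- rbind(m$atoms, far)
    m$atoms$serial <- seq_len(nrow(m$atoms)); rownames(m$atoms) <- NULL
    m
  }
  hp <- detect_hydrophobics(two_methane(3.5))
  expect_identical(nrow(hp), 1L)           # 2*1.7 + 0.25 = 3.65 >= 3.5
  expect_equal(hp$gap, 3.5 - 3.4, tolerance = 1e-6)
  expect_identical(nrow(detect_hydrophobics(two_methane(5.0))), 0L)
  # wrong elements: N...O pair at 3.0 A
  geo <- rbind(
    data.frame(name = "N", element = "N", x = 0, y = 0, z = 0,
               resname = "AAA", resseq = 1L),
    data.frame(name = "O", element = "O", x = 3, y = 0, z = 0,
               resname = "BBB", resseq = 2L))
  m <- rigidcryst:::structure_from_geom(geo)
  expect_identical(nrow(detect_hydrophobics(m)), 0L)
})

test_that("interaction detection is invariant under rigid motion", {
  m <- parse_pdb(make_toy_crystal("P 1", "rod", 5.64, 20, 20))
  sc <- build_supercell(build_unit_cell(m), 2, 1, 1)
  mm <- build_mechanical_model(sc)
  ## rotate everything by an arbitrary rotation + translation
  th <- 0.7; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- cbind(sc$atoms$x, sc$atoms$y, sc$atoms$z) %*% t(R)
  sc2 <- sc
  sc2$atoms$x <- xyz[, 1] + 5; sc2$atoms$y <- xyz[, 2] - 3
  sc2$atoms$z <- xyz[, 3] + 1
  mm2 <- build_mechanical_model(sc2)
  expect_identical(nrow(mm2$hbonds), nrow(mm$hbonds))
  expect_equal(mm2$hbonds$energy, mm$hbonds$energy, tolerance = 1e-9)
  expect_identical(nrow(mm2$hydrophobics), nrow(mm$hydrophobics))
})

test_that("curation edits add and remove hydrogen bonds reversibly", {
  m <- parse_pdb(make_toy_crystal("P 1", "rod", 5.64, 20, 20))
  sc <- build_supercell(build_unit_cell(m), 3, 1, 1)
  mm <- build_mechanical_model(sc)
  n0 <- nrow(mm$hbonds)
  labs <- sort(unique(sc$atoms$unit_label))
  edits <- sprintf("ADD_HBOND %s/1/N/%s %s/1/O/%s",
                   sc$atoms$chain_id[sc$atoms$unit_label == labs[1]][1], labs[1],
                   sc$atoms$chain_id[sc$atoms$unit_label == labs[3]][1], labs[3])
  mm2 <- apply_curation(mm, edits)
  expect_identical(nrow(mm2$hbonds), n0 + 1L)
  expect_true(any(mm2$hbonds$curated))
  del <- sub("ADD_HBOND", "DEL_HBOND", edits)
  mm3 <- apply_curation(mm2, del)
  expect_identical(nrow(mm3$hbonds), n0)
  expect_identical(mm3$hbonds$donor, mm$hbonds$donor)
  expect_error(apply_curation(mm, "ADD_HBOND Z/9/XX A/1/O"), "no atom")
})

test_that("curated bonds between copies symmetrize the decomposition", {
  m <- parse_pdb(make_toy_crystal("P 1", "rod", 5.64, 20, 20))
  sc <- build_supercell(build_unit_cell(m), 2, 1, 1)
  mm <- build_mechanical_model(sc)
  before <- rigid_decompose(mm)
  ## one detected inter-copy hbond (5 bars): copies not mutually rigid
  expect_identical(length(before$clusters), 2L)
  ## curated second bond brings the pair to the 6-bar cap: rigid
  chains <- vapply(split(sc$atoms$chain_id, sc$atoms$unit_label), `[`, "", 1)
  mm2 <- apply_curation(mm, sprintf("ADD_HBOND %s/1/O/%s %s/1/N/%s",
                                    chains[1], names(chains)[1],
                                    chains[2], names(chains)[2]))
  after <- rigid_decompose(mm2)
  expect_identical(length(after$clusters), 1L)
  expect_identical(after$sizes, nrow(sc$atoms))
})

test_that("naive hydrogen placement restores a donor", {
  m <- parse_pdb(make_toy_crystal("P 1", "rod", 5.64, 20, 20))
  bare <- m
  bare$atoms <- bare$atoms[bare$atoms$element != "H", ]
  bare$atoms$serial <- seq_len(nrow(bare$atoms)); rownames(bare$atoms) <- NULL
  placed <- place_hydrogens(bare)
  ## both bare heteroatoms (N and O) receive one hydrogen each
  expect_identical(nrow(placed$atoms), nrow(bare$atoms) + 2L)
  hs <- placed$atoms[placed$atoms$element == "H", ]
  n <- placed$atoms[placed$atoms$name == "N", ]
  dh <- sqrt((hs$x - n$x)^2 + (hs$y - n$y)^2 + (hs$z - n$z)^2)
  h <- hs[which.min(dh), ]
  expect_equal(min(dh), 1, tolerance = 1e-6)
  expect_gt(h$x, n$x)   # points away from the C neighbor
})
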