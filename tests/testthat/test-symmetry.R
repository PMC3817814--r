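test_that("cell geometry follows the standard orthogonalization", {
  g <- cell_geometry(crystal_card(10, 10, 10, 90, 90, 90))
  expect_equal(g$orthogonalization, 10 * diag(3), tolerance = 1e-12)
  expect_equal(cell_geometry(crystal_card(1, 1, 1, 90, 90, 90))$volume, 1)

  # closed-form volume equals |det| of the produced matrix
  g2 <- cell_geometry(crystal_card(10, 20, 30, 90, 120, 90))
  expect_equal(g2$volume, abs(det(g2$orthogonalization)),
               tolerance = 1e-9)
  ca <- cos(pi / 2); cb <- cos(120 * pi / 180); cg <- cos(pi / 2)
  expect_equal(g2$volume,
               10 * 20 * 30 * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg),
               tolerance = 1e-9)
  # a-vector along x, b in xy-plane; |a| matches the card
  expect_equal(g2$vectors[1, ], c(10, 0, 0))
  expect_equal(g2$vectors[2, 3], 0)
  # impossible angle combination
  expect_error(cell_geometry(crystal_card(10, 10, 10, 170, 10, 10)),
               "volume")
})

test_that("operation composition behaves as group algebra", {
  id <- sym_op(diag(3))
  two_z <- sym_op(diag(c(-1, -1, 1)))
  expect_equal(sym_compose(id, two_z)$rotation, two_z$rotation)
  expect_equal(sym_compose(two_z, two_z)$rotation, diag(3))
  # 4_1 screw about z composed four times reduces to the identity mod 1
  s41 <- parse_triplet("-y,x,z+1/4")
  acc <- s41
  for (k in 1:3) acc <- sym_compose(s41, acc)
  expect_equal(acc$rotation, diag(3))
  expect_equal(acc$translation, c(0, 0, 0))
  # mixed frames refuse
  expect_error(sym_compose(id, sym_op(diag(3), frame = "cartesian")),
               "frames")
})

test_that("operation classification distinguishes the allowed types", {
  expect_identical(sym_classify(sym_op(diag(3))), "identity")
  expect_identical(sym_classify(sym_op(diag(3), c(0.5, 0, 0))), "translation")
  expect_identical(sym_classify(sym_op(diag(c(1, -1, -1)), c(0.5, 0, 0))),
                   "screw_rotation")   # 2_1 axis
  expect_identical(sym_classify(sym_op(diag(c(1, -1, -1)))), "rotation")
  expect_identical(sym_classify(sym_op(diag(c(-1, 1, 1)))), "improper")
  # off-axis translation (location part) is still a pure rotation
  expect_identical(sym_classify(sym_op(diag(c(-1, -1, 1)), c(0.5, 0, 0))),
                   "rotation")
  expect_error(sym_classify(sym_op(2 * diag(3))), "det")
})

test_that("registry closure reproduces the published group orders", {
  expect_identical(length(space_group("P 21 21 21")$ops), 4L)
  expect_identical(length(space_group("P 31 2 1")$ops), 6L)
  expect_identical(length(space_group("P 1 21 1")$ops), 2L)
  expect_identical(length(space_group("P 41 21 2")$ops), 8L)
  # symbol normalization variants
  expect_identical(space_group("p41212")$itc_number,
                   space_group("P 41 21 2")$itc_number)
  expect_identical(space_group("P_21_21_21")$itc_number, 19L)
  # frozen textbook multiplicities across lattice systems and centerings
  known <- c("P 1" = 1L, "P -1" = 2L, "C 1 2 1" = 4L, "F 2 2 2" = 16L,
             "I 4" = 8L, "R 3" = 9L, "P 63 2 2" = 12L, "F 2 3" = 48L,
             "F m -3 m" = 192L, "I a -3 d" = 96L)
  for (sym in names(known))
    expect_identical(length(space_group(sym)$ops), known[[sym]],
                     info = sym)
  expect_error(space_group("P 9 9 9"), "nearest")
})

test_that("registry covers 230 groups, 65 Sohncke, 7 systems, 14 lattices", {
  reg <- space_groups()
  expect_identical(nrow(reg), 230L)
  expect_identical(sum(reg$sohncke), 65L)
  expect_identical(count_sohncke(), 65L)
  expect_identical(length(unique(reg$lattice_system)), 7L)
  expect_identical(length(bravais_classes()), 14L)
})

test_that("every sampled group is closed with identity and inverses", {
  for (sym in c("P 1 21 1", "P 21 21 21", "P 41 21 2", "P 31 2 1",
                "C 1 2 1", "P -1", "R 3", "F 2 3")) {
    ops <- space_group(sym)$ops
    keys <- vapply(ops, rigidcryst:::sym_key, "")
    expect_true(rigidcryst:::sym_key(sym_op(diag(3))) %in% keys, info = sym)
    for (p in ops) for (q in ops)
      expect_true(rigidcryst:::sym_key(sym_compose(p, q)) %in% keys,
                  info = sym)
    # inverses: for each op some q with p*q = identity
    idk <- rigidcryst:::sym_key(sym_op(diag(3)))
    for (p in ops)
      expect_true(any(vapply(ops, function(q)
        rigidcryst:::sym_key(sym_compose(p, q)) == idk, TRUE)), info = sym)
  }
})

test_that("Sohncke groups contain no improper operation and others do", {
  reg <- space_groups(compute = FALSE)
  sample_syms <- c("P 21 21 21", "P 31 2 1", "P 41 21 2", "I 2 2 2",
                   "P -1", "C 1 c 1", "F d -3 m", "P 63 2 2")
  for (sym in sample_syms) {
    sg <- space_group(sym)
    kinds <- vapply(sg$ops, sym_classify, "")
    if (sg$sohncke) expect_false("improper" %in% kinds, info = sym)
    else expect_true("improper" %in% kinds, info = sym)
  }
})

test_that("cartesian Sohncke operations are isometries", {
  geom <- cell_geometry(crystal_card(11, 13, 17, 90, 103, 90))
  ops <- space_group("P 1 21 1")$ops
  set.seed(7)
  pts <- matrix(runif(30, 0, 10), ncol = 3)
  ref <- sort(as.numeric(dist(pts)))
  for (op in ops) {
    cop <- sym_to_cartesian(op, geom)
    moved <- sym_apply(cop, pts)
    expect_equal(sort(as.numeric(dist(moved))), ref, tolerance = 1e-9)
  }
})

test_that("triplet rendering round-trips through the parser", {
  for (sym in c("P 21 21 21", "P 31 2 1", "R 3")) {
    for (op in space_group(sym)$ops) {
      back <- parse_triplet(sym_triplet(op))
      expect_equal(back$rotation, op$rotation)
      expect_equal(back$translation, op$translation)
    }
  }
})
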