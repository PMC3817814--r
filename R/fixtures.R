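## Synthetic fixtures with known ground truth.
##
## Small molecules with ideal covalent geometry (C-H 1.09 A, C-C 1.54 A,
## planar peptide units) and toy crystals in chosen space groups.  Every
## fixture is deterministic and carries its designed body/hinge/DOF counts
## in the "ground_truth" attribute, so downstream stages can be tested
## without any external structure files.

#' Generate a synthetic molecule
#'
#' Supported kinds:
#' \describe{
#'   \item{methane}{CH4; one rigid body, zero internal degrees of freedom.}
#'   \item{ethane}{H3C-CH3, staggered; two bodies sharing the C-C hinge, one
#'     internal degree of freedom.}
#'   \item{alkane_chain}{n-alkane with `n_units` carbons; `n_units` bodies
#'     and `n_units - 1` hinges.}
#'   \item{peptide_backbone}{`n_units` planar peptide units (formyl-capped
#'     polyglycine backbone) joined through alpha carbons; `2 n - 1` bodies
#'     and `2 n - 2` hinges (phi/psi rotations). For two peptide units this
#'     is the textbook three-bodies-two-hinges fragment.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param n_units chain length for alkane_chain / peptide_backbone.
#' @return A [parse_pdb]-style `pdb_structure` with attribute
#'   `"ground_truth"` (list: bodies, hinges, internal_dof).
#' @examples
#' make_molecule("ethane")
#' @export
make_molecule <- function(kind = c("methane", "ethane", "alkane_chain",
                                   "peptide_backbone"),
                          n_units = 2L) {
  kind <- match.arg(kind)
  n_units <- as.integer(n_units)
  if (n_units < 1) stop("make_molecule: n_units must be >= 1")
  geo <- switch(kind,
    methane = geom_methane(),
    ethane = geom_ethane(),
    alkane_chain = geom_alkane(n_units),
    peptide_backbone = geom_peptide(n_units))
  gt <- switch(kind,
    methane = list(bodies = 1L, hinges = 0L, internal_dof = 0L),
    ethane = list(bodies = 2L, hinges = 1L, internal_dof = 1L),
    alkane_chain = list(bodies = n_units, hinges = n_units - 1L,
                        internal_dof = n_units - 1L),
    peptide_backbone = list(bodies = 2L * n_units - 1L,
                            hinges = 2L * n_units - 2L,
                            internal_dof = 2L * n_units - 2L))
  m <- structure_from_geom(geo)
  attr(m, "ground_truth") <- gt
  m
}

structure_from_geom <- function(geo, chain = "A") {
  n <- nrow(geo)
  atoms <- data.frame(
    serial = seq_len(n), name = geo$name, altloc = " ",
    resname = geo$resname, chain_id = chain,
    resseq = geo$resseq, icode = " ",
    x = round(geo$x, 3), y = round(geo$y, 3), z = round(geo$z, 3),
    occupancy = 1, bfactor = 0, unit_label = "",
    element = geo$element, hetatm = FALSE, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, crystal = NULL, biomt = list(),
                 smtry = list(),
                 helix = parse_helix(character()),
                 sheet = parse_sheet(character())),
            class = "pdb_structure")
}

geom_row <- function(name, element, xyz, resname = "LIG", resseq = 1L) {
  data.frame(name = name, element = element, x = xyz[1], y = xyz[2],
             z = xyz[3], resname = resname, resseq = as.integer(resseq),
             stringsAsFactors = FALSE)
}

geom_methane <- function(center = c(0, 0, 0), resseq = 1L, idx = 1L) {
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  rbind(geom_row(paste0("C", idx), "C", center, "MTH", resseq),
        do.call(rbind, lapply(1:4, function(i)
          geom_row(paste0("H", idx, i), "H", center + 1.09 * dirs[i, ],
                   "MTH", resseq))))
}

geom_ethane <- function() {
  cc <- 1.54; ch <- 1.09
  zc <- ch * cos(109.47 * pi / 180); rr <- ch * sin(109.47 * pi / 180)
  g <- geom_row("C1", "C", c(0, 0, 0), "ETH")
  g <- rbind(g, geom_row("C2", "C", c(0, 0, cc), "ETH"))
  for (k in 0:2) {
    a <- 2 * pi * k / 3
    g <- rbind(g, geom_row(paste0("H1", k + 1), "H",
                           c(rr * cos(a), rr * sin(a), zc), "ETH"))
    b <- a + pi / 3
    g <- rbind(g, geom_row(paste0("H2", k + 1), "H",
                           c(rr * cos(b), rr * sin(b), cc - zc), "ETH"))
  }
  g
}

geom_alkane <- function(n) {
  if (n == 1) return(geom_methane())
  if (n == 2) return(geom_ethane())
  cc <- 1.54; ch <- 1.09
  th <- 109.47 * pi / 180
  dx <- cc * sin(th / 2); dy <- cc * cos(th / 2)
  pos <- t(vapply(seq_len(n), function(i)
    c((i - 1) * dx, (i %% 2) * dy, 0), numeric(3)))
  g <- NULL
  for (i in seq_len(n)) {
    g <- rbind(g, geom_row(paste0("C", i), "C", pos[i, ], "ALK"))
    up <- if (i %% 2 == 0) -1 else 1
    ## two out-of-plane hydrogens per carbon
    hdir1 <- c(0, up * 0.5, sqrt(0.75)); hdir2 <- c(0, up * 0.5, -sqrt(0.75))
    g <- rbind(g, geom_row(paste0("H", i, "A"), "H", pos[i, ] + ch * hdir1, "ALK"),
               geom_row(paste0("H", i, "B"), "H", pos[i, ] + ch * hdir2, "ALK"))
    if (i == 1)
      g <- rbind(g, geom_row("H1C", "H", pos[1, ] + ch * c(-sin(th / 2), -cos(th / 2) * up, 0), "ALK"))
    if (i == n) {
      upn <- if (n %% 2 == 0) -1 else 1
      g <- rbind(g, geom_row(paste0("H", n, "C"), "H",
                             pos[n, ] + ch * c(sin(th / 2), -cos(th / 2) * upn, 0), "ALK"))
    }
  }
  g
}

## Extended (all-planar, zigzag) peptide backbone:
## H0-C1(=O1)-N1(H)-CA1(H2)-C2(=O2)-N2(H)-CA2(H2)- ... -Cn(=On)-Nn(H)(H')
geom_peptide <- function(n) {
  lens <- c(CN = 1.33, NCA = 1.46, CAC = 1.52)
  half <- 32.5 * pi / 180                 # zigzag half-angle
  ## backbone walk: C1, N1, CA1, C2, N2, CA2, ..., Cn, Nn
  kinds <- character(); pos <- NULL
  p <- c(0, 0, 0); up <- 1
  add <- function(kind, q) { kinds <<- c(kinds, kind); pos <<- rbind(pos, q) }
  add("C", p)
  for (i in seq_len(n)) {
    p <- p + lens["CN"] * c(cos(half), up * sin(half), 0); up <- -up
    add("N", p)
    if (i == n) break
    p <- p + lens["NCA"] * c(cos(half), up * sin(half), 0); up <- -up
    add("CA", p)
    p <- p + lens["CAC"] * c(cos(half), up * sin(half), 0); up <- -up
    add("C", p)
  }
  g <- NULL
  nb <- nrow(pos)
  subst_dir <- function(i) {
    ## in-plane direction away from the backbone neighbors of atom i
    v <- c(0, 0, 0)
    for (j in c(i - 1, i + 1)) if (j >= 1 && j <= nb) {
      d <- pos[j, ] - pos[i, ]; v <- v + d / sqrt(sum(d^2))
    }
    -v / sqrt(sum(v^2))
  }
  unit_of <- cumsum(kinds == "C")         # residue number per backbone atom
  for (i in seq_len(nb)) {
    res <- unit_of[i]
    g <- rbind(g, geom_row(kinds[i], if (kinds[i] == "CA") "C" else kinds[i],
                           pos[i, ], "GLY", res))
    d <- subst_dir(i)
    if (kinds[i] == "C") {
      g <- rbind(g, geom_row("O", "O", pos[i, ] + 1.23 * d, "GLY", res))
      if (i == 1)        # formyl cap hydrogen
        g <- rbind(g, geom_row("H0", "H",
                               pos[i, ] + 1.09 * rot2(d, pi / 2), "GLY", res))
    } else if (kinds[i] == "N") {
      g <- rbind(g, geom_row("H", "H", pos[i, ] + 1.00 * d, "GLY", res))
      if (i == nb)       # amide cap: second hydrogen replaces the next CA
        g <- rbind(g, geom_row("HT", "H",
                               pos[i, ] + 1.00 * rot2(d, pi / 2), "GLY", res))
    } else {             # CA: two out-of-plane hydrogens
      g <- rbind(g,
        geom_row("HA1", "H", pos[i, ] + 1.09 * (0.4 * d + c(0, 0, 0.917)), "GLY", res),
        geom_row("HA2", "H", pos[i, ] + 1.09 * (0.4 * d + c(0, 0, -0.917)), "GLY", res))
    }
  }
  g
}

rot2 <- function(v, ang) {               # rotate an in-plane (xy) vector
  c(cos(ang) * v[1] - sin(ang) * v[2], sin(ang) * v[1] + cos(ang) * v[2], v[3])
}

## --- toy crystals ----------------------------------------------------------

#' Generate a toy crystal PDB file
#'
#' Writes a complete PDB text (CRYST1, REMARK 290 rows consistent with the
#' space-group registry closure, a REMARK 350 identity assembly, and one
#' motif placed in the asymmetric unit) so that the whole build-model-analyze
#' pipeline can run on a structure with controllable ground truth.
#'
#' Motifs:
#' \describe{
#'   \item{rod}{a rigid 4-atom O=C-N-H unit along +x: one hydrogen-bond
#'     donor (N-H) and one acceptor (O). With cell edge
#'     `a = gap + 3.64` the +a neighbor accepts a single linear hydrogen
#'     bond at H...A distance `gap`.}
#'   \item{ring}{cyclopropane (C3H6), a single rigid body offering only
#'     hydrophobic carbon contacts.}
#' }
#'
#' @param space_group Hermann-Mauguin symbol (must be in the registry).
#' @param motif `"rod"` or `"ring"`.
#' @param a,b,c cell edges in Angstroms (angles are 90 degrees).
#' @param frac_origin fractional position of the motif reference point;
#'   defaults to a space-group-appropriate position (on the screw axis for
#'   P 1 21 1, a general position otherwise).
#' @return character vector of PDB lines.
#' @export
make_toy_crystal <- function(space_group = "P 1", motif = c("rod", "ring"),
                             a = 30, b = 30, c = 30, frac_origin = NULL) {
  motif <- match.arg(motif)
  sg <- space_group(space_group)
  card <- crystal_card(a, b, c, space_group_symbol = sg$hm_symbol,
                       z_value = length(sg$ops))
  geom <- cell_geometry(card)
  geo <- switch(motif, rod = geom_rod(), ring = geom_ring())
  if (is.null(frac_origin)) {
    frac_origin <- if (normalize_hm(space_group) == "P1211")
      c(0, 0.25, 0) else c(0.15, 0.15, 0.15)
  }
  ext <- apply(abs(geo[, c("x", "y", "z")]), 2, max)
  if (any(2 * ext > c(a, b, c)))
    stop("make_toy_crystal: motif larger than the unit cell")
  shift <- drop(geom$orthogonalization %*% frac_origin)
  geo$x <- geo$x + shift[1]; geo$y <- geo$y + shift[2]; geo$z <- geo$z + shift[3]
  model <- structure_from_geom(geo)
  model$crystal <- card
  model$smtry <- lapply(seq_along(sg$ops), function(i) {
    op <- sym_to_cartesian(sg$ops[[i]], geom)
    transform_record("SMTRY", i, op$rotation, op$translation)
  })
  model$biomt <- list(`1` = list(
    chains = "A",
    transforms = list(transform_record("BIOMT", 1L, diag(3), c(0, 0, 0),
                                       assembly_id = 1L))))
  write_pdb(model)
}

geom_rod <- function() {
  rbind(geom_row("O", "O", c(-2.63, 0, 0), "RDA"),
        geom_row("C", "C", c(-1.40, 0, 0), "RDA"),
        geom_row("N", "N", c(0, 0, 0), "RDA"),
        geom_row("H", "H", c(1.01, 0, 0), "RDA"))
}

geom_ring <- function() {
  r <- 1.51 / sqrt(3)
  g <- NULL
  for (k in 0:2) {
    ang <- 2 * pi * k / 3
    cpos <- c(r * cos(ang), 0, r * sin(ang))
    rad <- c(cos(ang), 0, sin(ang))
    g <- rbind(g, geom_row(paste0("C", k + 1), "C", cpos, "CPR"))
    for (s in c(1, -1))
      g <- rbind(g, geom_row(paste0("H", k + 1, if (s > 0) "A" else "B"), "H",
                             cpos + 1.09 * (0.545 * rad + c(0, s * 0.838, 0)),
                             "CPR"))
  }
  g
}
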