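## Covalent bond inference and rigid-body partitioning.
##
## Bonds are inferred from interatomic distances against covalent radii.
## Each bond is classed either "locked" (its dihedral cannot rotate: peptide
## and other partial-double bonds, ring bonds, bonds to terminal atoms,
## disulfides) or "single_rotatable".  Contracting the locked bonds yields
## the rigid bodies; each remaining rotatable bond between two bodies is a
## hinge, and per the body-bar-hinge convention the two hinge atoms belong
## to both incident bodies.

## residue-template partial-double bonds (beyond peptide C-N and rings)
PARTIAL_DOUBLE <- list(
  ASP = list(c("CG", "OD1"), c("CG", "OD2")),
  GLU = list(c("CD", "OE1"), c("CD", "OE2")),
  ASN = list(c("CG", "OD1"), c("CG", "ND2")),
  GLN = list(c("CD", "OE1"), c("CD", "NE2")),
  ARG = list(c("CZ", "NE"), c("CZ", "NH1"), c("CZ", "NH2")))

#' Infer covalent bonds from geometry
#'
#' Two atoms are bonded iff their distance does not exceed the sum of their
#' covalent radii plus 0.4 Angstrom.  Bonds are classified `locked` when the
#' torsion about them is not a degree of freedom: peptide C-N bonds,
#' residue-template partial double bonds (carboxyl, amide, guanidinium),
#' any bond lying in a ring of the covalent graph, bonds to terminal
#' (single-neighbor) atoms, and disulfide S-S bonds (<= 2.3 A).  All other
#' bonds are `single_rotatable`.
#'
#' @param model `pdb_structure`.
#' @return data frame with columns `i`, `j` (atom row indices, i < j),
#'   `length` (Angstroms) and `order_class`.
#' @export
infer_covalent_bonds <- function(model) {
  at <- model$atoms
  rad <- covalent_radii()
  r <- rad[at$element]
  if (anyNA(r)) {
    warning("infer_covalent_bonds: unknown element(s) ",
            paste(unique(at$element[is.na(r)]), collapse = ", "),
            "; using 1.5 A covalent radius")
    r[is.na(r)] <- 1.5
  }
  maxcut <- 2 * max(r) + 0.4
  pr <- neighbor_pairs(cbind(at$x, at$y, at$z), maxcut)
  if (nrow(pr) == 0) stop("infer_covalent_bonds: no atom pairs in range")
  keep <- pr[, 3] <= r[pr[, 1]] + r[pr[, 2]] + 0.4
  bonds <- data.frame(i = as.integer(pr[keep, 1]),
                      j = as.integer(pr[keep, 2]),
                      length = pr[keep, 3], stringsAsFactors = FALSE)
  deg <- tabulate(c(bonds$i, bonds$j), nbins = nrow(at))
  if (any(deg > 8))
    stop("infer_covalent_bonds: atom with more than 8 bonds (corrupt input), ",
         "e.g. atom ", which(deg > 8)[1])

  locked <- rep(FALSE, nrow(bonds))
  ## terminal atoms
  locked <- locked | deg[bonds$i] == 1 | deg[bonds$j] == 1
  ## peptide / amide C-N by canonical atom naming
  nm_i <- at$name[bonds$i]; nm_j <- at$name[bonds$j]
  locked <- locked | (nm_i == "C" & nm_j == "N") | (nm_i == "N" & nm_j == "C")
  ## residue-template partial doubles (both atoms in the same residue)
  same_res <- at$chain_id[bonds$i] == at$chain_id[bonds$j] &
    at$resseq[bonds$i] == at$resseq[bonds$j] &
    at$unit_label[bonds$i] == at$unit_label[bonds$j]
  for (rn in names(PARTIAL_DOUBLE)) {
    for (pairnm in PARTIAL_DOUBLE[[rn]]) {
      hit <- same_res & at$resname[bonds$i] == rn &
        ((nm_i == pairnm[1] & nm_j == pairnm[2]) |
         (nm_i == pairnm[2] & nm_j == pairnm[1]))
      locked <- locked | hit
    }
  }
  ## disulfides
  locked <- locked | (at$element[bonds$i] == "S" & at$element[bonds$j] == "S" &
                        bonds$length <= 2.3)
  ## ring bonds: any edge not a bridge of the covalent graph lies in a cycle
  g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
  br <- igraph::bridges(g)
  in_ring <- rep(TRUE, nrow(bonds)); in_ring[as.integer(br)] <- FALSE
  locked <- locked | in_ring

  bonds$order_class <- ifelse(locked, "locked", "single_rotatable")
  bonds
}

## all pairs within `cutoff`, via a uniform grid (linear in atom count)
neighbor_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(numeric(0), 0, 3))
  if (n <= 400) {
    d <- as.matrix(stats::dist(xyz))
    idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    return(cbind(idx[, 1], idx[, 2], d[idx]))
  }
  cell <- pmax(cutoff, 1e-6)
  key <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  kid <- key[, 1] + 4096 * key[, 2] + 4096^2 * key[, 3]
  buckets <- split(seq_len(n), kid)
  keymat <- unique(key)
  lookup <- stats::setNames(seq_along(buckets), names(buckets))
  res_i <- integer(); res_j <- integer(); res_d <- numeric()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (b in seq_along(buckets)) {
    ii <- buckets[[b]]
    k0 <- key[ii[1], ]
    neigh <- integer()
    for (o in seq_len(nrow(offs))) {
      kk <- k0 + offs[o, ]
      hit <- lookup[as.character(kk[1] + 4096 * kk[2] + 4096^2 * kk[3])]
      if (!is.na(hit)) neigh <- c(neigh, buckets[[hit]])
    }
    neigh <- neigh[neigh > 0]
    for (a in ii) {
      cand <- neigh[neigh > a]
      if (!length(cand)) next
      dv <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[a, ])^2))
      ok <- dv <= cutoff
      res_i <- c(res_i, rep(a, sum(ok))); res_j <- c(res_j, cand[ok])
      res_d <- c(res_d, dv[ok])
    }
  }
  cbind(res_i, res_j, res_d)
}

#' Partition atoms into rigid bodies and hinges
#'
#' Contracts all locked bonds: each connected component of the locked
#' subgraph is one rigid body.  Every remaining rotatable bond joining two
#' bodies becomes a hinge, and its two atoms are added to both incident
#' bodies (the shared-hinge-atom convention used throughout the cluster
#' tables).  Single-atom bodies with exactly one incident rotatable bond are
#' merged into their unique neighbor (a lone atom cannot carry a torsion).
#'
#' @param model `pdb_structure`.
#' @param bonds covalent bond table from [infer_covalent_bonds]; computed if
#'   missing.
#' @return A `mech_model` list: `atoms`, `bonds`, `body_of` (primary body id
#'   per atom), `bodies` (list of atom index vectors, hinge atoms shared),
#'   `hinges` (data frame body1/body2/i/j), and empty `hbonds` /
#'   `hydrophobics` tables to be filled by the detectors.
#' @export
partition_bodies <- function(model, bonds = infer_covalent_bonds(model)) {
  n <- nrow(model$atoms)
  repeat {
    locked <- bonds$order_class == "locked"
    comp <- locked_components(n, bonds[locked, , drop = FALSE])
    sizes <- tabulate(comp)
    rot <- which(!locked)
    ## merge rule: single-atom body with exactly one rotatable bond
    rot_ci <- comp[bonds$i[rot]]; rot_cj <- comp[bonds$j[rot]]
    inc <- tabulate(c(rot_ci, rot_cj), nbins = length(sizes))
    fix <- rot[(sizes[rot_ci] == 1 & inc[rot_ci] == 1) |
                 (sizes[rot_cj] == 1 & inc[rot_cj] == 1)]
    if (!length(fix)) break
    bonds$order_class[fix] <- "locked"
  }
  rot <- which(bonds$order_class != "locked")
  b1 <- comp[bonds$i[rot]]; b2 <- comp[bonds$j[rot]]
  intra <- b1 == b2
  if (any(intra)) {       # ring rule: rotatable bond closing a locked cycle
    message("partition_bodies: ", sum(intra),
            " rotatable bond(s) inside a locked ring reclassified as locked")
    bonds$order_class[rot[intra]] <- "locked"
    rot <- rot[!intra]; b1 <- b1[!intra]; b2 <- b2[!intra]
  }
  hinges <- data.frame(body1 = pmin(b1, b2), body2 = pmax(b1, b2),
                       i = bonds$i[rot], j = bonds$j[rot])
  bodies <- split(seq_len(n), comp)
  ## shared-hinge-atom convention: both hinge atoms belong to both bodies
  for (h in seq_len(nrow(hinges))) {
    pair <- c(hinges$i[h], hinges$j[h])
    bodies[[hinges$body1[h]]] <- union(bodies[[hinges$body1[h]]], pair)
    bodies[[hinges$body2[h]]] <- union(bodies[[hinges$body2[h]]], pair)
  }
  structure(list(atoms = model$atoms, bonds = bonds, body_of = comp,
                 bodies = lapply(bodies, sort), hinges = hinges,
                 hbonds = empty_hbonds(), hydrophobics = empty_hydrophobics()),
            class = "mech_model")
}

locked_components <- function(n, locked_bonds) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(locked_bonds))
    g <- igraph::add_edges(g, rbind(locked_bonds$i, locked_bonds$j))
  igraph::components(g)$membership
}

#' @export
print.mech_model <- function(x, ...) {
  cat("<mech_model> ", nrow(x$atoms), " atoms, ", length(x$bodies),
      " bodies, ", nrow(x$hinges), " hinges, ", nrow(x$hbonds),
      " hbonds, ", nrow(x$hydrophobics), " hydrophobic contacts\n", sep = "")
  invisible(x)
}

#' Build the full mechanical model in one call
#'
#' Runs [infer_covalent_bonds], [partition_bodies], [detect_hbonds] and
#' [detect_hydrophobics] with the given parameters.
#'
#' @param model `pdb_structure` (hydrogens expected to be present).
#' @param energy_cutoff hydrogen-bond energy threshold, kcal/mol.
#' @param gap_tolerance hydrophobic gap beyond van der Waals contact, A.
#' @return `mech_model` with interactions attached.
#' @export
build_mechanical_model <- function(model, energy_cutoff = -1.0,
                                   gap_tolerance = 0.25) {
  bonds <- infer_covalent_bonds(model)
  mm <- partition_bodies(model, bonds)
  mm$hbonds <- detect_hbonds(model, bonds, energy_cutoff = energy_cutoff)
  mm$hydrophobics <- detect_hydrophobics(model, bonds,
                                         gap_tolerance = gap_tolerance)
  mm
}
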