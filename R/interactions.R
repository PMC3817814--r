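## Stabilizing interactions: hydrogen bonds, hydrophobic contacts,
## manual curation edits, and a naive hydrogen placer for fixtures.

empty_hbonds <- function()
  data.frame(donor = integer(), hydrogen = integer(), acceptor = integer(),
             energy = numeric(), inter_unit = logical(), curated = logical())

empty_hydrophobics <- function()
  data.frame(i = integer(), j = integer(), gap = numeric(),
             inter_unit = logical())

#' Detect hydrogen bonds
#'
#' Candidate geometry: donor D in {N, O, S} with a covalently bonded
#' hydrogen H, acceptor A in {N, O, S} with H...A <= 2.6 A, D...A <= 3.6 A
#' and angle D-H-A >= 90 degrees; acceptors covalently bonded to (or two
#' bonds from) the donor are excluded.  Each candidate is scored with a
#' Mayo-style energy
#' \deqn{E = V_0 [5 (R_0/R)^{12} - 6 (R_0/R)^{10}] \cos^4\theta}
#' with well depth V0 = 8 kcal/mol, equilibrium donor-acceptor distance
#' R0 = 2.8 A, R the D...A distance and theta the D-H-A angle; a bond is
#' kept iff `E <= energy_cutoff` (default -1 kcal/mol).
#'
#' @param model `pdb_structure`.
#' @param bonds covalent bond table (computed if missing).
#' @param energy_cutoff kcal/mol; more negative is stricter.
#' @return data frame: donor, hydrogen, acceptor (atom indices), energy,
#'   inter_unit (endpoints in different symmetry units), curated (FALSE),
#'   sorted by donor then acceptor.
#' @export
detect_hbonds <- function(model, bonds = infer_covalent_bonds(model),
                          energy_cutoff = -1.0) {
  at <- model$atoms
  adj <- bond_adjacency(nrow(at), bonds)
  don_el <- c("N", "O", "S")
  hyd <- which(at$element == "H")
  ## donor-hydrogen pairs
  dh <- NULL
  for (h in hyd) {
    heavy <- adj[[h]][at$element[adj[[h]]] %in% don_el]
    if (length(heavy)) dh <- rbind(dh, cbind(heavy[1], h))
  }
  acc <- which(at$element %in% don_el)
  if (is.null(dh) || length(acc) == 0) {
    if (length(acc) && any(at$element %in% don_el))
      warning("detect_hbonds: no hydrogens bonded to donor atoms; ",
              "0 hydrogen bonds (is the structure protonated?)")
    return(empty_hbonds())
  }
  xyz <- cbind(at$x, at$y, at$z)
  out <- empty_hbonds()
  for (r in seq_len(nrow(dh))) {
    d <- dh[r, 1]; h <- dh[r, 2]
    excl <- c(d, h, adj[[d]], unlist(adj[adj[[d]]]))  # 1-2 and 1-3 of donor
    a_ok <- setdiff(acc, excl)
    if (!length(a_ok)) next
    ha <- sqrt(colSums((t(xyz[a_ok, , drop = FALSE]) - xyz[h, ])^2))
    da <- sqrt(colSums((t(xyz[a_ok, , drop = FALSE]) - xyz[d, ])^2))
    sel <- ha <= 2.6 & da <= 3.6
    for (k in which(sel)) {
      a <- a_ok[k]
      v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
      cth <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      theta <- acos(pmin(1, pmax(-1, cth)))
      if (theta < pi / 2) next
      e <- mayo_energy(da[k], theta)
      if (e <= energy_cutoff)
        out <- rbind(out, data.frame(
          donor = d, hydrogen = h, acceptor = a, energy = e,
          inter_unit = at$unit_label[d] != at$unit_label[a],
          curated = FALSE))
    }
  }
  out[order(out$donor, out$acceptor), , drop = FALSE]
}

#' Mayo-style hydrogen-bond energy
#'
#' @param r_da donor-acceptor distance, Angstroms.
#' @param theta donor-hydrogen-acceptor angle, radians.
#' @param v0 well depth, kcal/mol.
#' @param r0 equilibrium donor-acceptor distance, Angstroms.
#' @return energy in kcal/mol (negative = favorable).
#' @export
mayo_energy <- function(r_da, theta, v0 = 8, r0 = 2.8) {
  x <- r0 / r_da
  v0 * (5 * x^12 - 6 * x^10) * cos(theta)^4
}

#' Detect hydrophobic contacts
#'
#' Carbon/sulfur atom pairs from different residues whose distance does not
#' exceed the sum of their van der Waals radii plus `gap_tolerance`
#' (default 0.25 A); pairs that are covalently bonded or share a covalent
#' neighbor are excluded.
#'
#' @param model `pdb_structure`.
#' @param bonds covalent bond table (computed if missing).
#' @param gap_tolerance Angstroms beyond van der Waals contact.
#' @return data frame: i, j (atom indices, i < j), gap (distance minus the
#'   van der Waals sum), inter_unit.
#' @export
detect_hydrophobics <- function(model, bonds = infer_covalent_bonds(model),
                                gap_tolerance = 0.25) {
  at <- model$atoms
  cs <- which(at$element %in% c("C", "S"))
  if (length(cs) < 2) return(empty_hydrophobics())
  vr <- vdw_radii()[at$element]
  cutoff <- 2 * max(vr[cs]) + gap_tolerance
  xyz <- cbind(at$x, at$y, at$z)
  pr <- neighbor_pairs(xyz[cs, , drop = FALSE], cutoff)
  if (nrow(pr) == 0) return(empty_hydrophobics())
  i <- cs[pr[, 1]]; j <- cs[pr[, 2]]; d <- pr[, 3]
  keep <- d <= vr[i] + vr[j] + gap_tolerance
  ## different residues only
  keep <- keep & !(at$chain_id[i] == at$chain_id[j] &
                     at$resseq[i] == at$resseq[j] &
                     at$unit_label[i] == at$unit_label[j])
  ## exclude 1-2 and 1-3 connected pairs
  adj <- bond_adjacency(nrow(at), bonds)
  for (k in which(keep)) {
    if (j[k] %in% adj[[i[k]]] ||
        length(intersect(adj[[i[k]]], adj[[j[k]]])))
      keep[k] <- FALSE
  }
  out <- data.frame(i = i[keep], j = j[keep],
                    gap = d[keep] - (vr[i] + vr[j])[keep],
                    inter_unit = at$unit_label[i[keep]] != at$unit_label[j[keep]])
  out[order(out$i, out$j), , drop = FALSE]
}

bond_adjacency <- function(n, bonds) {
  adj <- rep(list(integer()), n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], bonds$j[r])
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], bonds$i[r])
  }
  adj
}

#' Count interactions between symmetry units
#'
#' @param mm `mech_model` whose atoms carry unit labels.
#' @return data frame with one row per unordered unit-label pair that has at
#'   least one inter-unit interaction: unit1, unit2, hbonds, hydrophobics.
#' @export
count_interface_interactions <- function(mm) {
  at <- mm$atoms
  pair_key <- function(u1, u2)
    paste(pmin(u1, u2), pmax(u1, u2), sep = "|")
  keys <- c(
    if (nrow(mm$hbonds))
      pair_key(at$unit_label[mm$hbonds$donor],
               at$unit_label[mm$hbonds$acceptor])[mm$hbonds$inter_unit],
    character(0))
  hkeys <- c(
    if (nrow(mm$hydrophobics))
      pair_key(at$unit_label[mm$hydrophobics$i],
               at$unit_label[mm$hydrophobics$j])[mm$hydrophobics$inter_unit],
    character(0))
  all_keys <- sort(unique(c(keys, hkeys)))
  if (!length(all_keys))
    return(data.frame(unit1 = character(), unit2 = character(),
                      hbonds = integer(), hydrophobics = integer()))
  parts <- strsplit(all_keys, "|", fixed = TRUE)
  data.frame(unit1 = vapply(parts, `[`, "", 1),
             unit2 = vapply(parts, `[`, "", 2),
             hbonds = as.integer(table(factor(keys, all_keys))),
             hydrophobics = as.integer(table(factor(hkeys, all_keys))))
}

## --- curation --------------------------------------------------------------

#' Parse curation edits
#'
#' Line-oriented format, one edit per line:
#' \preformatted{ADD_HBOND chain/resseq/atom chain/resseq/atom
#' DEL_HBOND chain/resseq/atom chain/resseq/atom}
#' An optional fourth slash-field selects the symmetry unit
#' (`A/12/OG1/2`). Blank lines and lines starting with `#` are ignored.
#'
#' @param lines character vector (or a path passed through [readLines]).
#' @return data frame of edits.
#' @export
read_curation <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(action = character(), a = character(), b = character()))
  toks <- strsplit(lines, "\\s+")
  bad <- vapply(toks, length, 0L) != 3
  if (any(bad)) stop("read_curation: malformed line: ", lines[bad][1])
  data.frame(action = vapply(toks, `[`, "", 1), a = vapply(toks, `[`, "", 2),
             b = vapply(toks, `[`, "", 3), stringsAsFactors = FALSE)
}

resolve_atom <- function(at, spec) {
  f <- strsplit(spec, "/", fixed = TRUE)[[1]]
  if (length(f) < 3) stop("curation: bad atom spec '", spec, "'")
  unit_ok <- if (length(f) >= 4) at$unit_label == f[4] else TRUE
  hit <- which(at$chain_id == f[1] & at$resseq == as.integer(f[2]) &
                 at$name == f[3] & unit_ok)
  if (!length(hit))
    stop("curation: no atom matching '", spec, "'")
  hit[1]
}

#' Apply curation edits to a mechanical model
#'
#' `ADD_HBOND` inserts a hydrogen bond between the named atoms (tagged
#' `curated`, energy `NA`); `DEL_HBOND` removes any hydrogen bond between
#' them (either orientation).  Everything else in the model is untouched.
#'
#' @param mm `mech_model`.
#' @param edits data frame from [read_curation] (or a character vector of
#'   edit lines).
#' @return the edited `mech_model`, with an `"edit_log"` attribute.
#' @export
apply_curation <- function(mm, edits) {
  if (is.character(edits)) edits <- read_curation(edits)
  at <- mm$atoms
  log <- character()
  for (r in seq_len(nrow(edits))) {
    ia <- resolve_atom(at, edits$a[r]); ib <- resolve_atom(at, edits$b[r])
    if (edits$action[r] == "ADD_HBOND") {
      mm$hbonds <- rbind(mm$hbonds, data.frame(
        donor = ia, hydrogen = NA_integer_, acceptor = ib, energy = NA_real_,
        inter_unit = at$unit_label[ia] != at$unit_label[ib], curated = TRUE))
      log <- c(log, paste("added hbond", edits$a[r], "->", edits$b[r]))
    } else if (edits$action[r] == "DEL_HBOND") {
      drop <- (mm$hbonds$donor == ia & mm$hbonds$acceptor == ib) |
        (mm$hbonds$donor == ib & mm$hbonds$acceptor == ia)
      mm$hbonds <- mm$hbonds[!drop, , drop = FALSE]
      log <- c(log, paste("removed", sum(drop), "hbond(s)",
                          edits$a[r], "--", edits$b[r]))
    } else stop("apply_curation: unknown action ", edits$action[r])
  }
  rownames(mm$hbonds) <- NULL
  attr(mm, "edit_log") <- log
  mm
}

#' Naive hydrogen placement
#'
#' Adds a hydrogen at 1.0 A to every N/O/S atom that has at least one heavy
#' covalent neighbor and no bonded hydrogen, in the direction opposite the
#' mean of its neighbor directions (ideal for sp2/sp3 centers with a single
#' missing substituent).  When that direction is degenerate a seeded
#' arbitrary perpendicular is used.  This is a deliberately simple placer
#' for fixtures and sanity checks; crystallographic work should use a
#' dedicated placement program and pass in protonated coordinates.
#'
#' @param model `pdb_structure` lacking some polar hydrogens.
#' @param seed integer controlling the arbitrary-direction fallback.
#' @return `pdb_structure` with hydrogens appended.
#' @export
place_hydrogens <- function(model, seed = 1L) {
  bonds <- infer_covalent_bonds(model)
  at <- model$atoms
  adj <- bond_adjacency(nrow(at), bonds)
  rng <- local({ set.seed(seed); function() stats::runif(3, -1, 1) })
  add <- NULL
  for (d in which(at$element %in% c("N", "O", "S"))) {
    nb <- adj[[d]]
    if (!length(nb) || any(at$element[nb] == "H")) next
    dirs <- sweep(cbind(at$x[nb], at$y[nb], at$z[nb]), 2,
                  c(at$x[d], at$y[d], at$z[d]))
    dirs <- dirs / sqrt(rowSums(dirs^2))
    v <- -colSums(dirs)
    if (sqrt(sum(v^2)) < 1e-6) {
      u <- dirs[1, ]; w <- rng()
      v <- w - sum(w * u) * u
    }
    v <- v / sqrt(sum(v^2))
    add <- rbind(add, data.frame(
      serial = 0L, name = paste0("H", d), altloc = " ",
      resname = at$resname[d], chain_id = at$chain_id[d],
      resseq = at$resseq[d], icode = " ",
      x = at$x[d] + v[1], y = at$y[d] + v[2], z = at$z[d] + v[3],
      occupancy = 1, bfactor = 0, unit_label = at$unit_label[d],
      element = "H", hetatm = at$hetatm[d], stringsAsFactors = FALSE))
  }
  if (!is.null(add)) {
    model$atoms <- rbind(at, add)
    model$atoms$serial <- seq_len(nrow(model$atoms))
    rownames(model$atoms) <- NULL
  }
  model
}
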