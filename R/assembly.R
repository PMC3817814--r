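## Assembly building: biological assemblies (REMARK 350 BIOMT), unit cells
## (space-group closure in fractional coordinates) and finite supercells
## (lattice translations).  Every generated copy gets a fresh chain label
## and a `unit_label` recording which transform/cell produced it, so that
## cluster tables can attribute rigidity to symmetry units.

#' Assembly specification
#'
#' @param mode `"biological"`, `"unit_cell"` or `"supercell"`.
#' @param assembly_id biological assembly number (mode `"biological"`).
#' @param subset optional transform indices for partial assemblies.
#' @param repeats integer vector (na, nb, nc) for mode `"supercell"`.
#' @return an `assembly_spec` list.
#' @export
assembly_spec <- function(mode = c("biological", "unit_cell", "supercell"),
                          assembly_id = 1L, subset = NULL,
                          repeats = c(1L, 1L, 1L)) {
  mode <- match.arg(mode)
  repeats <- as.integer(repeats)
  if (length(repeats) != 3 || any(repeats < 1))
    stop("assembly_spec: repeats must be three positive integers")
  structure(list(mode = mode, assembly_id = as.integer(assembly_id),
                 subset = subset, repeats = repeats),
            class = "assembly_spec")
}

#' Build an assembly according to a specification
#'
#' Dispatches to [build_biological_assembly], [build_unit_cell] or
#' [build_unit_cell] + [build_supercell].
#'
#' @param model `pdb_structure`.
#' @param spec `assembly_spec`.
#' @return `pdb_structure`.
#' @export
build_assembly <- function(model, spec) {
  switch(spec$mode,
         biological = build_biological_assembly(model, spec$assembly_id,
                                                spec$subset),
         unit_cell = build_unit_cell(model),
         supercell = build_supercell(build_unit_cell(model),
                                     spec$repeats[1], spec$repeats[2],
                                     spec$repeats[3]))
}

## fresh chain labels: A-Z, a-z, 0-9, then two-character labels AA, AB, ...
allocate_chain_labels <- function(n) {
  if (n <= 62) return(CHAIN_ALPHABET[seq_len(n)])
  extra <- apply(expand.grid(CHAIN_ALPHABET, CHAIN_ALPHABET)[, 2:1], 1, paste,
                 collapse = "")
  c(CHAIN_ALPHABET, extra)[seq_len(n)]
}

## apply cartesian transforms to a structure, one labeled copy per transform
replicate_atoms <- function(model, rotations, translations, unit_labels) {
  at <- model$atoms
  chains <- unique(at$chain_id)
  ncopy <- length(rotations)
  labels <- allocate_chain_labels(ncopy * length(chains))
  chain_map <- character()
  copies <- vector("list", ncopy)
  ss_h <- NULL; ss_s <- NULL
  for (k in seq_len(ncopy)) {
    xyz <- cbind(at$x, at$y, at$z) %*% t(rotations[[k]])
    xyz <- sweep(xyz, 2, -translations[[k]])
    cp <- at
    cp$x <- round(xyz[, 1], 6); cp$y <- round(xyz[, 2], 6)
    cp$z <- round(xyz[, 3], 6)
    new_chains <- labels[(k - 1) * length(chains) + seq_along(chains)]
    names(new_chains) <- chains
    cp$chain_id <- new_chains[cp$chain_id]
    cp$unit_label <- unit_labels[k]
    chain_map[paste0(unit_labels[k], ":", chains)] <- new_chains
    copies[[k]] <- cp
    if (nrow(model$helix)) {
      h <- model$helix; h$chain_id <- new_chains[h$chain_id]; ss_h <- rbind(ss_h, h)
    }
    if (nrow(model$sheet)) {
      s <- model$sheet; s$chain_id <- new_chains[s$chain_id]; ss_s <- rbind(ss_s, s)
    }
  }
  out <- model
  out$atoms <- do.call(rbind, copies)
  out$atoms$serial <- seq_len(nrow(out$atoms))
  rownames(out$atoms) <- NULL
  out$helix <- if (is.null(ss_h)) parse_helix(character()) else ss_h
  out$sheet <- if (is.null(ss_s)) parse_sheet(character()) else ss_s
  attr(out, "chain_map") <- chain_map
  out
}

#' Build a biological assembly from REMARK 350 transforms
#'
#' Applies each BIOMT transform of the requested assembly to the targeted
#' chains (cartesian frame), producing one uniquely relabeled copy per
#' transform with `unit_label` equal to the transform index.  A single
#' identity transform returns the input atoms unchanged.
#'
#' @param model `pdb_structure` with a `biomt` entry for `assembly_id`.
#' @param assembly_id which biological assembly to build.
#' @param subset optional transform indices (partial assembly).
#' @return `pdb_structure`; the chain relabeling map is in attribute
#'   `"chain_map"`.
#' @export
build_biological_assembly <- function(model, assembly_id = 1L, subset = NULL) {
  key <- as.character(assembly_id)
  if (is.null(model$biomt[[key]]))
    stop("build_biological_assembly: no assembly ", assembly_id,
         "; available: ",
         if (length(model$biomt)) paste(names(model$biomt), collapse = ", ")
         else "none")
  set <- model$biomt[[key]]
  transforms <- set$transforms
  if (!is.null(subset)) {
    idx <- vapply(transforms, `[[`, 0L, "index")
    miss <- setdiff(subset, idx)
    if (length(miss))
      stop("build_biological_assembly: subset transform(s) ",
           paste(miss, collapse = ", "), " not in assembly ", assembly_id)
    transforms <- transforms[idx %in% subset]
  }
  if (length(transforms) == 0)
    stop("build_biological_assembly: assembly ", assembly_id,
         " has no transforms")
  src <- model
  if (length(set$chains))
    src$atoms <- model$atoms[model$atoms$chain_id %in% set$chains, ,
                             drop = FALSE]
  if (nrow(src$atoms) == 0)
    stop("build_biological_assembly: targeted chains not present")
  if (length(transforms) == 1 && is_identity_transform(transforms[[1]]))
    return(src)
  replicate_atoms(src,
                  lapply(transforms, `[[`, "rotation"),
                  lapply(transforms, `[[`, "translation"),
                  vapply(transforms, function(tr) as.character(tr$index), ""))
}

is_identity_transform <- function(tr) {
  max(abs(tr$rotation - diag(3))) < 1e-6 && max(abs(tr$translation)) < 1e-6
}

#' Build the unit cell by space-group symmetry
#'
#' Converts the asymmetric unit to fractional coordinates, applies every
#' operation of the space-group closure (resolved from the CRYST1 symbol in
#' the registry) and converts back, producing one labeled copy per
#' operation.  Copies are not wrapped into the unit box by default; with
#' `wrap = TRUE` each copy is shifted by the lattice translation that puts
#' its centroid into [0,1)^3.  When REMARK 290 SMTRY records are present
#' they are cross-checked against the registry closure (warning on
#' mismatch).
#'
#' @param model `pdb_structure` with a crystal card.
#' @param wrap logical; wrap copy centroids into the unit box.
#' @return `pdb_structure` with `length(ops)` labeled copies.
#' @export
build_unit_cell <- function(model, wrap = FALSE) {
  if (is.null(model$crystal))
    stop("build_unit_cell: model has no CRYST1 crystal information")
  sg <- space_group(model$crystal$space_group_symbol)
  geom <- cell_geometry(model$crystal)
  check_smtry(model$smtry, sg, geom)
  at <- model$atoms
  frac <- cart_to_frac(cbind(at$x, at$y, at$z), geom)
  rots <- list(); trans <- list()
  for (i in seq_along(sg$ops)) {
    op <- sg$ops[[i]]
    tr <- op$translation
    if (wrap) {
      centroid <- drop(op$rotation %*% colMeans(frac)) + tr
      tr <- tr - floor(centroid)
    }
    cart_op <- sym_to_cartesian(sym_op_raw(op$rotation, tr), geom)
    rots[[i]] <- cart_op$rotation; trans[[i]] <- cart_op$translation
  }
  out <- replicate_atoms(model, rots, trans, as.character(seq_along(sg$ops)))
  out$crystal <- model$crystal
  out
}

## sym_op without fractional translation reduction (wrap shifts can be < 0)
sym_op_raw <- function(rotation, translation) {
  structure(list(rotation = rotation, translation = translation,
                 frame = "fractional"), class = "sym_op")
}

check_smtry <- function(smtry, sg, geom) {
  if (length(smtry) == 0) return(invisible(TRUE))
  if (length(smtry) != length(sg$ops)) {
    warning("build_unit_cell: REMARK 290 lists ", length(smtry),
            " operators but the ", sg$hm_symbol, " closure has ",
            length(sg$ops))
    return(invisible(FALSE))
  }
  carts <- lapply(sg$ops, sym_to_cartesian, geom = geom)
  ok <- vapply(smtry, function(rec) {
    any(vapply(carts, function(op)
      max(abs(op$rotation - rec$rotation)) < 1e-3 &&
        max(abs(op$translation - rec$translation)) < 1e-2, TRUE))
  }, TRUE)
  if (!all(ok))
    warning("build_unit_cell: ", sum(!ok), " SMTRY operator(s) do not match ",
            "the registry closure of ", sg$hm_symbol)
  invisible(all(ok))
}

#' Build a finite supercell by lattice translations
#'
#' Translates the unit cell by `i * a + j * b + k * c` for
#' `i < na, j < nb, k < nc`, extending each copy's unit label with the cell
#' index (e.g. `"2"` in cell (1,0,0) becomes `"2100"`).
#'
#' @param cell `pdb_structure` produced by [build_unit_cell] (must carry the
#'   crystal card).
#' @param na,nb,nc positive repeat counts along the three cell vectors.
#' @return `pdb_structure` with `na * nb * nc` translated cell copies.
#' @export
build_supercell <- function(cell, na = 1L, nb = 1L, nc = 1L) {
  if (is.null(cell$crystal))
    stop("build_supercell: input does not carry crystal information")
  na <- as.integer(na); nb <- as.integer(nb); nc <- as.integer(nc)
  if (any(c(na, nb, nc) < 1))
    stop("build_supercell: repeats must be >= 1")
  if (all(c(na, nb, nc) == 1L)) return(cell)
  geom <- cell_geometry(cell$crystal)
  vec <- geom$vectors
  n_total <- na * nb * nc * nrow(cell$atoms)
  if (n_total > 99999)
    warning("build_supercell: ", n_total, " atoms exceed the PDB writer ",
            "capacity of 99,999 serials; the in-memory model is returned")
  copies <- list(); ss_h <- NULL; ss_s <- NULL
  at <- cell$atoms
  base_labels <- at$unit_label
  if (all(!nzchar(base_labels))) base_labels <- rep("1", nrow(at))
  chains <- unique(at$chain_id)
  all_labels <- allocate_chain_labels(na * nb * nc * length(chains))
  idx <- 0L
  for (k in 0:(nc - 1)) for (j in 0:(nb - 1)) for (i in 0:(na - 1)) {
    idx <- idx + 1L
    shift <- i * vec[1, ] + j * vec[2, ] + k * vec[3, ]
    cp <- at
    cp$x <- at$x + shift[1]; cp$y <- at$y + shift[2]; cp$z <- at$z + shift[3]
    cp$unit_label <- paste0(base_labels, i, j, k)
    new_chains <- all_labels[(idx - 1) * length(chains) + seq_along(chains)]
    names(new_chains) <- chains
    cp$chain_id <- new_chains[cp$chain_id]
    copies[[idx]] <- cp
    if (nrow(cell$helix)) {
      h <- cell$helix; h$chain_id <- new_chains[h$chain_id]
      ss_h <- rbind(ss_h, h)
    }
    if (nrow(cell$sheet)) {
      s <- cell$sheet; s$chain_id <- new_chains[s$chain_id]
      ss_s <- rbind(ss_s, s)
    }
  }
  out <- cell
  out$atoms <- do.call(rbind, copies)
  out$atoms$serial <- seq_len(nrow(out$atoms))
  rownames(out$atoms) <- NULL
  out$helix <- if (is.null(ss_h)) parse_helix(character()) else ss_h
  out$sheet <- if (is.null(ss_s)) parse_sheet(character()) else ss_s
  out
}
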