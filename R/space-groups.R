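## Space-group registry.
##
## The package ships a plain-text table (inst/extdata/space_groups.tsv) with
## one row per standard-setting space group: ITC number, Hermann-Mauguin
## symbol, crystal system, centering letter, a small set of generator
## triplets, and the published group order (used only as a consistency
## check).  Everything else -- the full operator list, the Sohncke flag, the
## operation classification -- is computed at run time by generator closure.

.sg_env <- new.env(parent = emptyenv())

sg_table <- function() {
  if (is.null(.sg_env$table)) {
    path <- system.file("extdata", "space_groups.tsv", package = "rigidcryst")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c("integer", "character", "character",
                                            "character", "character", "integer"))
    tab$key <- normalize_hm(tab$hm_symbol)
    .sg_env$table <- tab
  }
  .sg_env$table
}

#' Normalize a Hermann-Mauguin symbol
#'
#' Collapses the spacing/underscore/case variants seen in PDB files
#' (`"P 21 21 21"`, `"P212121"`, `"p_21_21_21"`) onto one canonical key, and
#' maps the `H`-centering aliases used by some PDB entries for rhombohedral
#' groups (e.g. `"H 3 2"`) to the standard `R` symbols.
#'
#' @param symbol character vector of symbols.
#' @return canonical keys.
#' @export
normalize_hm <- function(symbol) {
  key <- toupper(gsub("[ _]", "", symbol))
  key <- sub(":.*$", "", key)                 # drop setting suffixes like :H
  h_alias <- c(H3 = "R3", `H-3` = "R-3", H32 = "R32", H312 = "P312",
               H321 = "P321", `H3M` = "R3M", `H3C` = "R3C")
  hit <- match(key, names(h_alias))
  key[!is.na(hit)] <- h_alias[hit[!is.na(hit)]]
  key
}

#' The 230 space groups
#'
#' Returns the registry as a data frame with, per group: ITC number, symbol,
#' lattice system (the seven crystal groups, with trigonal groups assigned to
#' the rhombohedral or hexagonal lattice by their centering), centering
#' letter, group order (computed by closure), and whether the group is
#' Sohncke (all operations proper, i.e. compatible with chiral molecules).
#'
#' @param compute logical; if `TRUE` (default) closures are run and the
#'   `order` and `sohncke` columns are genuine computations, otherwise they
#'   are `NA` (fast listing).
#' @return data frame with 230 rows.
#' @export
space_groups <- function(compute = TRUE) {
  tab <- sg_table()
  out <- data.frame(number = tab$number, hm_symbol = tab$hm_symbol,
                    lattice_system = lattice_system(tab$crystal_system,
                                                    tab$centering),
                    centering = tab$centering, stringsAsFactors = FALSE)
  if (compute) {
    entries <- lapply(tab$hm_symbol, space_group)
    out$order <- vapply(entries, function(e) length(e$ops), 0L)
    out$sohncke <- vapply(entries, function(e) e$sohncke, TRUE)
  } else {
    out$order <- NA_integer_; out$sohncke <- NA
  }
  out
}

lattice_system <- function(crystal_system, centering) {
  ifelse(crystal_system == "trigonal",
         ifelse(centering == "R", "rhombohedral", "hexagonal"),
         crystal_system)
}

#' Look up a space group and compute its operator closure
#'
#' @param symbol Hermann-Mauguin symbol (spacing/case/underscore variants
#'   accepted) or ITC number (1-230).
#' @return A `space_group_entry`: symbol, number, lattice system, centering,
#'   `generators` (list of [sym_op]s), `ops` (full closure), and `sohncke`
#'   flag computed from the closure determinants.
#' @examples
#' sg <- space_group("P 21 21 21")
#' length(sg$ops)   # 4
#' @export
space_group <- function(symbol) {
  tab <- sg_table()
  if (is.numeric(symbol)) {
    i <- match(as.integer(symbol), tab$number)
    if (is.na(i)) stop("space_group: no group numbered ", symbol)
  } else {
    key <- normalize_hm(symbol)
    i <- match(key, tab$key)
    if (is.na(i)) {
      near <- tab$hm_symbol[order(utils::adist(key, tab$key))][1:3]
      stop("space_group: unknown symbol '", symbol, "'; nearest: ",
           paste(near, collapse = ", "))
    }
  }
  cache_key <- as.character(tab$number[i])
  if (!is.null(.sg_env$entries[[cache_key]]))
    return(.sg_env$entries[[cache_key]])
  gen_str <- tab$generators[i]
  gens <- if (nzchar(gen_str))
    lapply(strsplit(gen_str, ";", fixed = TRUE)[[1]], parse_triplet)
  else list()
  ops <- sym_closure(gens)
  if (length(ops) != tab$multiplicity[i])
    stop("space_group: closure of ", tab$hm_symbol[i], " has ", length(ops),
         " operations, expected ", tab$multiplicity[i],
         " (registry inconsistency)")
  entry <- structure(
    list(hm_symbol = tab$hm_symbol[i], itc_number = tab$number[i],
         lattice_system = lattice_system(tab$crystal_system[i],
                                         tab$centering[i]),
         centering = tab$centering[i], generators = gens, ops = ops,
         sohncke = all(vapply(ops, function(o) det(o$rotation), 0) > 0)),
    class = "space_group_entry")
  if (is.null(.sg_env$entries)) .sg_env$entries <- list()
  .sg_env$entries[[cache_key]] <- entry
  entry
}

#' @export
print.space_group_entry <- function(x, ...) {
  cat("<space_group> ", x$hm_symbol, " (#", x$itc_number, "), ",
      length(x$ops), " operations, ",
      if (x$sohncke) "Sohncke" else "non-Sohncke", "\n", sep = "")
  invisible(x)
}

#' Count the Sohncke space groups
#'
#' Runs the generator closure for all 230 groups and counts those whose
#' operations all have determinant +1. Proteins, being chiral, crystallize
#' only in these groups.
#'
#' @return integer (65 for the standard registry).
#' @export
count_sohncke <- function() {
  sum(space_groups(compute = TRUE)$sohncke)
}

#' Bravais lattice classes represented in the registry
#'
#' Combines the lattice system with the centering class (the A/B/C
#' base-centerings count as one class) to enumerate the 14 Bravais lattices.
#'
#' @return character vector of distinct lattice-class labels.
#' @export
bravais_classes <- function() {
  tab <- sg_table()
  cen <- ifelse(tab$centering %in% c("A", "B", "C"), "C", tab$centering)
  sort(unique(paste(lattice_system(tab$crystal_system, tab$centering),
                    cen, sep = "-")))
}
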