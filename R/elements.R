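## Element data.
##
## Covalent radii follow Cordero et al. (2008), Dalton Trans. 2832; van der
## Waals radii follow Bondi (1964), J. Phys. Chem. 68:441 (with common
## extensions for metals).  Both tables ship as plain-text TSV under
## inst/extdata and are loaded once per session.

.elem_env <- new.env(parent = emptyenv())

load_radii <- function(which) {
  key <- paste0(which, "_radii")
  if (is.null(.elem_env[[key]])) {
    path <- system.file("extdata", paste0(key, ".tsv"), package = "rigidcryst")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    .elem_env[[key]] <- stats::setNames(tab$radius, tab$element)
  }
  .elem_env[[key]]
}

#' Covalent radii (Angstroms) by element symbol
#' @return named numeric vector.
#' @export
covalent_radii <- function() load_radii("covalent")

#' Van der Waals radii (Angstroms) by element symbol
#' @return named numeric vector.
#' @export
vdw_radii <- function() load_radii("vdw")
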