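## PDB-format reading and writing.
##
## Fixed-width column parsing per the PDB v3.3 layout.  The parser captures
## what the assembly builder needs beyond atoms: the CRYST1 cell, the
## crystallographic symmetry operators of REMARK 290 (SMTRY) and the
## biological-assembly transforms of REMARK 350 (BIOMT), plus HELIX/SHEET
## ranges.  Atom provenance across generated symmetry copies is carried in
## the `unit_label` field, stored in the segment-identifier columns (73-76)
## so that it survives a write/parse round trip.

#' Read and parse a PDB file
#'
#' @param file path to a PDB-format file.
#' @param remove_waters drop HETATM water records (HOH/WAT/DOD). Default TRUE.
#' @return A `pdb_structure`; see [parse_pdb].
#' @export
read_pdb <- function(file, remove_waters = TRUE) {
  parse_pdb(readLines(file, warn = FALSE), remove_waters = remove_waters)
}

#' Parse PDB-format text
#'
#' Captures ATOM/HETATM records (column-based), the CRYST1 card, REMARK 290
#' SMTRY and REMARK 350 BIOMT transform blocks, and HELIX/SHEET annotations.
#' Alternate-location duplicates of the same atom are resolved by keeping
#' the highest-occupancy conformer (ties: first encountered).
#'
#' @param lines character vector of PDB lines (a single string with embedded
#'   newlines is also accepted).
#' @param remove_waters drop water HETATM records. Default TRUE.
#' @return A `pdb_structure` list with elements `atoms` (data frame),
#'   `crystal` ([crystal_card] or NULL), `biomt` (per-assembly transform
#'   sets), `smtry` (list of transforms), `helix`, `sheet`.
#' @export
parse_pdb <- function(lines, remove_waters = TRUE) {
  if (length(lines) == 1 && grepl("\n", lines, fixed = TRUE))
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("parse_pdb: no ATOM/HETATM records found")

  al <- lines[is_atom]
  f <- function(from, to) trimws(substr(al, from, to))
  num <- function(from, to) suppressWarnings(as.numeric(f(from, to)))
  atoms <- data.frame(
    serial = decode_serial(f(7, 11)),
    name = f(13, 16),
    altloc = substr(al, 17, 17),
    resname = f(18, 20),
    chain_id = trimws(substr(al, 22, 22)),
    resseq = suppressWarnings(as.integer(f(23, 26))),
    icode = substr(al, 27, 27),
    x = num(31, 38), y = num(39, 46), z = num(47, 54),
    occupancy = num(55, 60), bfactor = num(61, 66),
    unit_label = f(73, 76),
    element = f(77, 78),
    hetatm = substr(al, 1, 6) == "HETATM",
    stringsAsFactors = FALSE)
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$bfactor[is.na(atoms$bfactor)] <- 0
  ## element fallback: first letter of the atom name field (cols 13-16;
  ## a leading digit means a hydrogen like 1HB2)
  blank <- !nzchar(atoms$element)
  if (any(blank)) {
    nm <- gsub("[^A-Za-z]", "", atoms$name[blank])
    two <- toupper(substr(nm, 1, 2))
    el <- ifelse(two %in% names(covalent_radii()), two,
                 toupper(substr(nm, 1, 1)))
    ## names like "CA" (alpha carbon) start in column 14; col 13 blank => 1-char element
    one_char <- substr(al[blank], 13, 13) == " "
    el[one_char] <- toupper(substr(nm[one_char], 1, 1))
    atoms$element[blank] <- el
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("parse_pdb: non-finite atom coordinates")
  if (remove_waters)
    atoms <- atoms[!(atoms$hetatm & atoms$resname %in% c("HOH", "WAT", "DOD")), ]
  atoms <- resolve_altloc(atoms)
  if (nrow(atoms) == 0) stop("parse_pdb: no atoms left after filtering")
  rownames(atoms) <- NULL

  crystal <- parse_cryst1(lines[rec == "CRYST1"])
  smtry <- parse_transforms(lines[startsWith(lines, "REMARK 290")],
                            "SMTRY", source = "SMTRY")
  biomt <- parse_remark350(lines[startsWith(lines, "REMARK 350")])
  helix <- parse_helix(lines[rec == "HELIX "])
  sheet <- parse_sheet(lines[rec == "SHEET "])

  structure(list(atoms = atoms, crystal = crystal, biomt = biomt,
                 smtry = smtry, helix = helix, sheet = sheet),
            class = "pdb_structure")
}

resolve_altloc <- function(atoms) {
  dup_key <- paste(atoms$chain_id, atoms$resseq, atoms$icode, atoms$name,
                   atoms$unit_label)
  if (!anyDuplicated(dup_key)) { atoms$altloc <- " "; return(atoms) }
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), dup_key), function(idx) {
    idx[which.max(atoms$occupancy[idx])]   # ties: first encountered
  }), use.names = FALSE)
  atoms <- atoms[sort(keep), ]
  atoms$altloc <- " "
  atoms
}

parse_cryst1 <- function(line) {
  if (length(line) == 0) return(NULL)
  line <- line[1]
  vals <- suppressWarnings(as.numeric(c(
    substr(line, 7, 15), substr(line, 16, 24), substr(line, 25, 33),
    substr(line, 34, 40), substr(line, 41, 47), substr(line, 48, 54))))
  sym <- trimws(substr(line, 56, 66))
  z <- suppressWarnings(as.integer(trimws(substr(line, 67, 70))))
  if (any(is.na(vals)) || any(vals[1:3] <= 0) ||
      any(vals[4:6] <= 0) || any(vals[4:6] >= 180)) {
    warning("parse_pdb: malformed CRYST1 record; crystal information dropped")
    return(NULL)
  }
  crystal_card(vals[1], vals[2], vals[3], vals[4], vals[5], vals[6],
               space_group_symbol = sym,
               z_value = if (is.na(z)) 1L else z)
}

## Parse 3-row transform blocks (SMTRY1..3 / BIOMT1..3).  Rows are joined by
## their serial number into one rotation + translation (Angstrom frame).
parse_transforms <- function(lines, tag, source, assembly_id = NA_integer_) {
  pat <- paste0("^", tag, "[123]$")
  rows <- list()
  for (ln in lines) {
    lab <- trimws(substr(ln, 14, 19))
    if (!grepl(pat, lab)) next
    toks <- strsplit(trimws(substr(ln, 20, 80)), "\\s+")[[1]]
    if (length(toks) < 5) next
    rows[[length(rows) + 1L]] <- list(row = as.integer(substr(lab, 6, 6)),
                                      index = as.integer(toks[1]),
                                      vals = as.numeric(toks[2:5]))
  }
  if (length(rows) == 0) return(list())
  idx <- vapply(rows, `[[`, 0L, "index")
  out <- list()
  for (i in sort(unique(idx))) {
    sel <- rows[idx == i]
    rn <- vapply(sel, `[[`, 0L, "row")
    if (!setequal(rn, 1:3)) {
      warning("parse_pdb: incomplete ", source, " transform ", i, "; skipped")
      next
    }
    m <- do.call(rbind, lapply(1:3, function(r) sel[[which(rn == r)]]$vals))
    out[[length(out) + 1L]] <- transform_record(
      source = source, index = i, rotation = m[, 1:3], translation = m[, 4],
      assembly_id = assembly_id)
  }
  out
}

parse_remark350 <- function(lines) {
  biomt <- list()
  cur_id <- NA_integer_; cur_chains <- character()
  flush_chains <- function() {
    if (!is.na(cur_id)) {
      key <- as.character(cur_id)
      if (is.null(biomt[[key]]))
        biomt[[key]] <<- list(chains = character(), transforms = list())
      biomt[[key]]$chains <<- unique(c(biomt[[key]]$chains, cur_chains))
    }
  }
  block <- character()
  flush_block <- function() {
    if (length(block) && !is.na(cur_id)) {
      key <- as.character(cur_id)
      tr <- parse_transforms(block, "BIOMT", "BIOMT", assembly_id = cur_id)
      biomt[[key]]$transforms <<- c(biomt[[key]]$transforms, tr)
    }
    block <<- character()
  }
  for (ln in lines) {
    body <- substr(ln, 11, nchar(ln))
    if (grepl("BIOMOLECULE:", body, fixed = TRUE)) {
      flush_block()
      cur_id <- as.integer(trimws(sub(".*BIOMOLECULE:", "", body)))
      cur_chains <- character()
      key <- as.character(cur_id)
      if (is.null(biomt[[key]]))
        biomt[[key]] <- list(chains = character(), transforms = list())
    } else if (grepl("TO CHAINS:", body, fixed = TRUE) ||
               grepl("AND CHAINS:", body, fixed = TRUE)) {
      cur_chains <- trimws(strsplit(sub(".*CHAINS:", "", body), ",")[[1]])
      cur_chains <- cur_chains[nzchar(cur_chains)]
      flush_chains()
    } else if (grepl("BIOMT[123]", substr(ln, 14, 19))) {
      block <- c(block, ln)
    }
  }
  flush_block()
  biomt
}

#' Transform record (BIOMT / SMTRY)
#'
#' @param source `"BIOMT"` or `"SMTRY"`.
#' @param index transform serial within its block.
#' @param rotation 3x3 matrix (cartesian frame, as stored in PDB remarks).
#' @param translation length-3 vector, Angstroms.
#' @param assembly_id biological assembly id (BIOMT only).
#' @return a `transform_record` list.
#' @export
transform_record <- function(source, index, rotation, translation,
                             assembly_id = NA_integer_) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (any(!is.finite(rotation)) || any(!is.finite(translation)))
    stop("transform_record: non-finite entries")
  if (source == "SMTRY") {
    err <- max(abs(crossprod(rotation) - diag(3)))
    if (err > 1e-4 || det(rotation) < 0)
      warning("transform_record: SMTRY rotation not proper-orthogonal (err ",
              format(err), ")")
  }
  structure(list(source = source, assembly_id = assembly_id,
                 index = as.integer(index), rotation = rotation,
                 translation = as.numeric(translation)),
            class = "transform_record")
}

parse_helix <- function(lines) {
  if (length(lines) == 0)
    return(data.frame(chain_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  data.frame(chain_id = trimws(substr(lines, 20, 20)),
             start = as.integer(trimws(substr(lines, 22, 25))),
             end = as.integer(trimws(substr(lines, 34, 37))),
             stringsAsFactors = FALSE)
}

parse_sheet <- function(lines) {
  if (length(lines) == 0)
    return(data.frame(chain_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  data.frame(chain_id = trimws(substr(lines, 22, 22)),
             start = as.integer(trimws(substr(lines, 23, 26))),
             end = as.integer(trimws(substr(lines, 34, 37))),
             stringsAsFactors = FALSE)
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat("<pdb_structure> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain_id)), " chain(s)", sep = "")
  if (!is.null(x$crystal))
    cat(", cell ", x$crystal$a, "x", x$crystal$b, "x", x$crystal$c,
        " (", x$crystal$space_group_symbol, ")", sep = "")
  nu <- length(unique(x$atoms$unit_label))
  if (nu > 1) cat(", ", nu, " symmetry units", sep = "")
  cat("\n")
  invisible(x)
}

## --- writing ---------------------------------------------------------------

CHAIN_ALPHABET <- c(LETTERS, letters, as.character(0:9))

#' Write a structure in PDB format
#'
#' Emits fixed-width ATOM/HETATM records plus CRYST1, REMARK 290/350 blocks
#' and HELIX/SHEET annotations, so that the output re-parses to an
#' equivalent structure.  The PDB format caps atom serials at 99,999 and
#' chain identifiers at one character; larger models are handled per
#' `overflow_policy`:
#' \describe{
#'   \item{error}{refuse, naming the capacity limit (default);}
#'   \item{wrap}{serials restart at 1 past 99,999, with a warning;}
#'   \item{hybrid}{serials above 99,999 use hybrid-36 encoding (A0000...),
#'     which keeps the 5-column width and is re-read by [parse_pdb].}
#' }
#' Chain labels are remapped onto the documented single-character cycle
#' A-Z, a-z, 0-9; with more than 62 chains the cycle restarts (warning).
#' The label map is attached as attribute `"chain_map"` of the return value.
#'
#' @param model `pdb_structure`.
#' @param file optional path; if NULL the lines are returned invisibly only.
#' @param overflow_policy `"error"`, `"wrap"` or `"hybrid"`.
#' @return character vector of PDB lines (invisible when `file` given), with
#'   attribute `chain_map` (named vector: model chain -> written chain).
#' @export
write_pdb <- function(model, file = NULL,
                      overflow_policy = c("error", "wrap", "hybrid")) {
  overflow_policy <- match.arg(overflow_policy)
  at <- model$atoms
  if (is.null(at) || nrow(at) == 0) stop("write_pdb: empty model")
  n <- nrow(at)
  if (n > 99999 && overflow_policy == "error")
    stop("write_pdb: ", n, " atoms exceed the PDB capacity of 99,999 ",
         "atom serials; use overflow_policy 'wrap' or 'hybrid'")

  chains <- unique(at$chain_id)
  map <- CHAIN_ALPHABET[(seq_along(chains) - 1L) %% 62L + 1L]
  if (length(chains) > 62)
    warning("write_pdb: ", length(chains),
            " chains exceed the 62-label alphabet; labels recycled")
  names(map) <- chains
  wchain <- map[at$chain_id]

  serial <- seq_len(n)
  if (n > 99999) {
    if (overflow_policy == "wrap") {
      warning("write_pdb: atom serials wrapped past 99,999")
      sfield <- sprintf("%5d", (serial - 1L) %% 99999L + 1L)
    } else {
      sfield <- encode_hybrid36(serial)
    }
  } else sfield <- sprintf("%5d", serial)

  seg <- at$unit_label
  if (any(nchar(seg) > 4)) {
    warning("write_pdb: unit labels longer than 4 characters truncated")
    seg <- substr(seg, 1, 4)
  }
  lines <- sprintf("%-6s%s %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
                   ifelse(at$hetatm, "HETATM", "ATOM"),
                   sfield, format_atom_name(at$name, at$element), " ",
                   at$resname, wchain, at$resseq %% 10000L,
                   substr(paste0(at$icode, " "), 1, 1),
                   at$x, at$y, at$z, at$occupancy, at$bfactor, seg,
                   sprintf("%2s", at$element))

  header <- character()
  if (!is.null(model$crystal)) {
    cc <- model$crystal
    header <- c(header, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
      cc$a, cc$b, cc$c, cc$alpha, cc$beta, cc$gamma,
      cc$space_group_symbol, cc$z_value))
  }
  header <- c(format_remark350(model$biomt, map), header)
  header <- c(format_transform_block(model$smtry, "REMARK 290", "SMTRY"), header)
  header <- c(header, format_ss(model$helix, "HELIX", map),
              format_ss(model$sheet, "SHEET", map))

  out <- c(header, lines, "END")
  attr(out, "chain_map") <- map
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

format_atom_name <- function(name, element) {
  ## PDB convention: 1-char element symbols start in column 14
  ifelse(nchar(element) == 1 & nchar(name) < 4,
         sprintf(" %-3s", name), sprintf("%-4s", name))
}

format_transform_block <- function(transforms, remark, tag) {
  if (length(transforms) == 0) return(character())
  unlist(lapply(transforms, function(tr) {
    sprintf("%s   %s%1d %3d%10.6f%10.6f%10.6f%15.5f",
            remark, tag, 1:3, tr$index,
            tr$rotation[, 1], tr$rotation[, 2], tr$rotation[, 3],
            tr$translation)
  }))
}

format_remark350 <- function(biomt, chain_map) {
  if (length(biomt) == 0) return(character())
  out <- character()
  for (key in names(biomt)) {
    set <- biomt[[key]]
    out <- c(out, sprintf("REMARK 350 BIOMOLECULE: %s", key))
    ch <- set$chains
    if (length(ch)) {
      ch <- ifelse(ch %in% names(chain_map), chain_map[ch], ch)
      out <- c(out, paste0("REMARK 350 APPLY THE FOLLOWING TO CHAINS: ",
                           paste(ch, collapse = ", ")))
    }
    out <- c(out, format_transform_block(set$transforms, "REMARK 350", "BIOMT"))
  }
  out
}

format_ss <- function(ss, kind, map) {
  if (is.null(ss) || nrow(ss) == 0) return(character())
  ch <- ifelse(ss$chain_id %in% names(map), map[ss$chain_id], ss$chain_id)
  if (kind == "HELIX")
    sprintf("HELIX  %3d %3s GLY %1s %4d  GLY %1s %4d  1%36d",
            seq_len(nrow(ss)), sprintf("%3d", seq_len(nrow(ss))), ch,
            ss$start, ch, ss$end, ss$end - ss$start + 1L)
  else
    sprintf("SHEET  %3d   S 1 GLY %1s%4d  GLY %1s%4d  0",
            seq_len(nrow(ss)), ch, ss$start, ch, ss$end)
}

## hybrid-36 serial encoding (5-column field)
encode_hybrid36 <- function(x) {
  d36 <- c(0:9, LETTERS)
  enc <- function(v, width) {
    out <- character(length(v))
    for (k in seq_along(v)) {
      n <- v[k]; s <- ""
      repeat { s <- paste0(d36[n %% 36 + 1], s); n <- n %/% 36; if (n == 0) break }
      out[k] <- formatC(s, width = width)
    }
    out
  }
  ifelse(x <= 99999, sprintf("%5d", x), enc(x - 100000 + 10 * 36^4, 5))
}

decode_serial <- function(s) {
  n <- suppressWarnings(as.integer(s))
  bad <- is.na(n) & nzchar(s)
  if (any(bad)) {
    dec <- function(str) {
      digs <- match(strsplit(str, "")[[1]], c(0:9, LETTERS)) - 1L
      sum(digs * 36^rev(seq_along(digs) - 1L)) - 10 * 36^4 + 100000
    }
    n[bad] <- vapply(s[bad], dec, 0)
  }
  n
}
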