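## Cluster-size tabulation across assembly levels, dominant/significant
## labeling, cross-level aggregation detection, and the seven-case
## classification of crystal rigidity behavior.

#' Tabulate a rigid cluster decomposition
#'
#' @param dec `rigid_decomposition`.
#' @param level_label one of `"AU"`, `"BU"`, `"1x1x1"`, `"2x1x1"`,
#'   `"2x2x1"` or any custom label.
#' @return A `cluster_table`: `histogram` (named integer vector, names are
#'   cluster sizes in atoms), `level_label`, `total_atoms`.
#' @export
cluster_table <- function(dec, level_label = "AU") {
  h <- table(dec$sizes)
  structure(list(histogram = stats::setNames(as.integer(h),
                                             names(h)),
                 level_label = level_label,
                 total_atoms = dec$n_atoms),
            class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  cat("<cluster_table> level ", x$level_label, ", ", x$total_atoms,
      " atoms\n", sep = "")
  df <- data.frame(size = as.integer(names(x$histogram)),
                   count = unname(x$histogram))
  print(df[order(df$size), ], row.names = FALSE)
  invisible(x)
}

table_sizes <- function(tab) as.integer(names(tab$histogram))

#' Label dominant and significant clusters
#'
#' Significant clusters are those of at least `significant_threshold` atoms
#' (default 20; smaller clusters typically belong to flexible regions and
#' are treated as background).  The largest cluster is dominant iff it is at
#' least `dominance_ratio` (default 3) times the next-largest significant
#' size.
#'
#' @param tab `cluster_table`.
#' @param significant_threshold atoms.
#' @param dominance_ratio multiplicative margin for dominance.
#' @return A `cluster_labels` list: `significant` (sizes, descending),
#'   `dominant` (size or NA), plus the parameters used.
#' @export
label_clusters <- function(tab, significant_threshold = 20,
                           dominance_ratio = 3.0) {
  sizes <- sort(table_sizes(tab), decreasing = TRUE)
  sig <- sizes[sizes >= significant_threshold]
  dominant <- NA_integer_
  if (length(sig) == 1) {
    dominant <- sig[1]
  } else if (length(sig) > 1) {
    ## the largest size must dominate the runner-up, and must be unique
    runner <- sig[2]
    if (tab$histogram[as.character(sig[1])] == 1L &&
        sig[1] >= dominance_ratio * runner)
      dominant <- sig[1]
  }
  structure(list(significant = unname(sig), dominant = unname(dominant),
                 significant_threshold = significant_threshold,
                 dominance_ratio = dominance_ratio),
            class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat("<cluster_labels> dominant:",
      if (is.na(x$dominant)) "none" else x$dominant,
      "| significant:",
      if (length(x$significant)) paste(x$significant, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Deviation from expected n-fold scaling
#'
#' When a structure grows by a factor n without new inter-unit coupling,
#' every cluster count should grow by the same factor.  This reports where
#' a derived level deviates from the n-fold copy of a base level:
#' `new_sizes` are sizes whose count exceeds n times the base count (or
#' that are absent from the base), and `merged_mass` is the total number of
#' atoms in derived clusters larger than the base's largest cluster --
#' the signature of rigid bodies aggregating across unit interfaces.
#'
#' @param base,derived `cluster_table`s.
#' @param n expected multiplicity of `derived` relative to `base`.
#' @return list with `new_sizes` (data frame size/excess) and
#'   `merged_mass` (atoms).
#' @export
scaling_deviation <- function(base, derived, n) {
  stopifnot(n >= 1)
  bs <- base$histogram; ds <- derived$histogram
  sizes <- as.integer(names(ds))
  base_cnt <- ifelse(names(ds) %in% names(bs), bs[names(ds)], 0L)
  excess <- unname(ds) - n * base_cnt
  new_idx <- which(excess > 0)
  new_sizes <- data.frame(size = sizes[new_idx],
                          excess = as.integer(excess[new_idx]))
  max_base <- if (length(bs)) max(as.integer(names(bs))) else 0L
  big <- sizes > max_base
  merged_mass <- sum(sizes[big] * unname(ds)[big])
  list(new_sizes = new_sizes, merged_mass = as.integer(merged_mass))
}

#' Classify crystal rigidity behavior
#'
#' Assigns one of seven behavior cases from the cluster tables of the four
#' assembly levels (asymmetric unit, unit cell, 2x1x1 and 2x2x1 crystals).
#' "Aggregation" at a level means clusters larger than anything at the
#' reference level appear there ([scaling_deviation] `merged_mass > 0`);
#' the unit cell is compared against the AU, the crystals against the unit
#' cell.  Rules are evaluated in order; the first that fires wins:
#' \enumerate{
#'   \item aggregation at the unit cell and in both crystals;
#'   \item aggregation at the unit cell only, with a dominant cell cluster;
#'   \item no aggregation anywhere (pure n-fold scaling);
#'   \item aggregation at the cell and in the 2x2x1 but not the 2x1x1
#'     crystal;
#'   \item same dominant size in AU and cell, aggregation in both crystals;
#'   \item a cell cluster spanning multiple asymmetric units with no
#'     further aggregation in the crystals;
#'   \item otherwise unclassified.
#' }
#'
#' @param au,cell,c211,c221 `cluster_table`s for the four levels.
#' @param significant_threshold,dominance_ratio passed to [label_clusters].
#' @return A `behavior_class`: `case_id` (1-7) and an `evidence` list.
#' @export
classify_behavior <- function(au, cell, c211, c221,
                              significant_threshold = 20,
                              dominance_ratio = 3.0) {
  n_cell <- max(1L, round(cell$total_atoms / au$total_atoms))
  agg_cell <- scaling_deviation(au, cell, n_cell)$merged_mass > 0
  agg_211 <- scaling_deviation(cell, c211, 2)$merged_mass > 0
  agg_221 <- scaling_deviation(cell, c221, 4)$merged_mass > 0
  lab_au <- label_clusters(au, significant_threshold, dominance_ratio)
  lab_cell <- label_clusters(cell, significant_threshold, dominance_ratio)
  max_au <- max(table_sizes(au)); max_cell <- max(table_sizes(cell))
  case_id <-
    if (agg_cell && agg_211 && agg_221) 1L
    else if (agg_cell && !agg_211 && !agg_221 && !is.na(lab_cell$dominant)) 2L
    else if (!agg_cell && !agg_211 && !agg_221 && max_cell <= max_au) 3L
    else if (agg_cell && !agg_211 && agg_221) 4L
    else if (!agg_cell && max_cell == max_au && agg_211 && agg_221) 5L
    else if (agg_cell && !agg_211 && !agg_221) 6L
    else 7L
  structure(list(case_id = case_id,
                 evidence = list(
                   aggregation = c(cell = agg_cell, x211 = agg_211,
                                   x221 = agg_221),
                   dominant = c(AU = lab_au$dominant,
                                cell = lab_cell$dominant),
                   largest = c(AU = max_au, cell = max_cell,
                               x211 = max(table_sizes(c211)),
                               x221 = max(table_sizes(c221))),
                   units_per_cell = n_cell)),
            class = "behavior_class")
}

BEHAVIOR_CASES <- c(
  "dominant cluster aggregation at all levels",
  "dominant cluster aggregation at the unit cell level",
  "no combining of rigid bodies in unit cell nor in larger crystals",
  "aggregation in unit cell and 2x2x1 crystal, but not 2x1x1",
  "same dominant cluster in AU and unit cell, aggregation in crystals",
  "cell-spanning cluster without further aggregation in crystals",
  "other; unclassified")

#' @export
print.behavior_class <- function(x, ...) {
  cat("<behavior_class> case ", x$case_id, ": ",
      BEHAVIOR_CASES[x$case_id], "\n", sep = "")
  invisible(x)
}

#' Render a cluster table as text or JSON-ready list
#'
#' @param tabs list of `cluster_table`s (e.g. the four levels).
#' @return data frame in the size-by-level layout used by the case-study
#'   tables: one row per size, one count column per level.
#' @export
cluster_report <- function(tabs) {
  sizes <- sort(unique(unlist(lapply(tabs, table_sizes))))
  out <- data.frame(size = sizes)
  for (tb in tabs) {
    cnt <- integer(length(sizes))
    hit <- match(names(tb$histogram), as.character(sizes))
    cnt[hit] <- unname(tb$histogram)
    out[[tb$level_label]] <- cnt
  }
  out
}
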