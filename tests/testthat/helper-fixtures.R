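# shared helpers: hand-built cluster tables, brute-force geometry checks

mk_table <- function(sizes, counts, level = "AU",
                     total = sum(sizes * counts)) {
  structure(list(histogram = stats::setNames(as.integer(counts),
                                             as.character(sizes)),
                 level_label = level, total_atoms = as.integer(total)),
            class = "cluster_table")
}

# sorted multiset of pairwise distances of an atom subset
dist_multiset <- function(atoms, idx = seq_len(nrow(atoms))) {
  sort(as.numeric(dist(cbind(atoms$x, atoms$y, atoms$z)[idx, , drop = FALSE])))
}

# brute-force hydrogen-bond count from raw coordinates, independent of
# detect_hbonds' candidate search: enumerates every N/O/S donor-H and
# N/O/S acceptor, applies the published geometric gates and energy formula
brute_hbond_count <- function(atoms, cutoff = -1.0) {
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  don_el <- c("N", "O", "S")
  n <- nrow(atoms)
  cnt <- 0L
  for (h in which(atoms$element == "H")) {
    dists <- sqrt(colSums((t(xyz) - xyz[h, ])^2))
    dcand <- which(atoms$element %in% don_el & dists < 1.3)
    if (!length(dcand)) next
    d <- dcand[which.min(dists[dcand])]
    for (a in which(atoms$element %in% don_el)) {
      if (a == d) next
      ha <- sqrt(sum((xyz[a, ] - xyz[h, ])^2))
      da <- sqrt(sum((xyz[a, ] - xyz[d, ])^2))
      if (ha > 2.6 || da > 3.6) next
      v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
      th <- acos(max(-1, min(1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2)))))
      if (th < pi / 2) next
      if (mayo_energy(da, th) <= cutoff) cnt <- cnt + 1L
    }
  }
  cnt
}

# random small body-bar multigraph for property tests
random_bb_graph <- function(seed, max_v = 5, max_bars = 14) {
  set.seed(seed)
  V <- sample(2:max_v, 1)
  ne <- sample(1:8, 1)
  ed <- data.frame(u = sample(V, ne, TRUE), v = sample(V, ne, TRUE),
                   bars = sample(1:4, ne, TRUE))
  ed <- ed[ed$u != ed$v, , drop = FALSE]
  while (nrow(ed) && sum(ed$bars) > max_bars)
    ed$bars <- pmax(1L, ed$bars %/% 2L)
  if (!nrow(ed)) return(NULL)
  bb_graph(V, ed)
}

write_fixture <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}
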