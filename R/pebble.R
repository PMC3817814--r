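## Body-bar rigidity via the (6,6) pebble game.
##
## A rigid body in 3-D has 6 degrees of freedom; a system of V bodies has
## 6V, of which 6 are trivial rigid-body motions.  Constraints are modeled
## as bars between bodies: a hinge (shared rotatable bond) removes all but
## one relative DOF and counts 5 bars, a hydrogen bond counts 5, a
## hydrophobic tether 2 (all configurable).  By Tay's theorem the generic
## rigidity of such a framework is governed by (6,6)-sparsity: a set of bars
## is independent iff every subset of bodies S spans at most 6|S| - 6 bars.
## The pebble game computes the rank of this count matroid incrementally.

#' Bar-count policy
#'
#' @param hinge,hbond,hydrophobic,curated bars assigned to each constraint
#'   origin. Defaults follow the FIRST/KINARI convention: 5/5/2, curated
#'   hydrogen bonds like detected ones.
#' @return named integer vector.
#' @export
bar_policy <- function(hinge = 5L, hbond = 5L, hydrophobic = 2L,
                       curated = hbond) {
  c(hinge = as.integer(hinge), hbond = as.integer(hbond),
    hydrophobic = as.integer(hydrophobic), curated = as.integer(curated))
}

#' Build the body-bar multigraph of a mechanical model
#'
#' Vertices are rigid bodies; every hinge, hydrogen bond and hydrophobic
#' contact contributes bars between the bodies containing its endpoint
#' atoms.  Parallel constraints between the same body pair accumulate, with
#' the total capped at 6 (more than 6 bars between two bodies is never
#' independent).  Constraints whose endpoints fall in the same body are
#' dropped as redundant.
#'
#' @param mm `mech_model`.
#' @param policy bar counts from [bar_policy].
#' @return A `body_bar_graph`: `n` (vertex count), `edges` (data frame u, v,
#'   bars, origin), `bodies` and `atoms` carried through for cluster mapping.
#' @export
body_bar_graph <- function(mm, policy = bar_policy()) {
  stopifnot(inherits(mm, "mech_model"))
  bo <- mm$body_of
  con <- data.frame(u = integer(), v = integer(), origin = character())
  if (nrow(mm$hinges))
    con <- rbind(con, data.frame(u = mm$hinges$body1, v = mm$hinges$body2,
                                 origin = "hinge"))
  if (nrow(mm$hbonds))
    con <- rbind(con, data.frame(u = bo[mm$hbonds$donor],
                                 v = bo[mm$hbonds$acceptor],
                                 origin = ifelse(mm$hbonds$curated,
                                                 "curated", "hbond")))
  if (nrow(mm$hydrophobics))
    con <- rbind(con, data.frame(u = bo[mm$hydrophobics$i],
                                 v = bo[mm$hydrophobics$j],
                                 origin = "hydrophobic"))
  con <- con[con$u != con$v, , drop = FALSE]
  if (nrow(con)) {
    uu <- pmin(con$u, con$v); vv <- pmax(con$u, con$v)
    con$u <- uu; con$v <- vv
    con$bars <- bar_policy_lookup(policy, con$origin)
    key <- paste(con$u, con$v)
    agg <- lapply(split(con, key), function(d)
      data.frame(u = d$u[1], v = d$v[1], bars = min(6L, sum(d$bars)),
                 origin = paste(sort(unique(d$origin)), collapse = "+")))
    edges <- do.call(rbind, agg)
    edges <- edges[order(edges$u, edges$v), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(u = integer(), v = integer(), bars = integer(),
                        origin = character())
  }
  structure(list(n = length(mm$bodies), edges = edges,
                 bodies = mm$bodies, atoms = mm$atoms),
            class = "body_bar_graph")
}

bar_policy_lookup <- function(policy, origin) {
  unname(policy[origin])
}

#' Construct a bare body-bar graph
#'
#' Convenience constructor for tests and direct rigidity questions.
#'
#' @param n number of bodies.
#' @param edges data frame or matrix with columns u, v, bars.
#' @return `body_bar_graph`.
#' @export
bb_graph <- function(n, edges = NULL) {
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(u = integer(), v = integer(), bars = integer(),
                        origin = character())
  } else {
    edges <- as.data.frame(edges)
    if (is.null(edges$origin)) edges$origin <- "bar"
    stopifnot(all(edges$u != edges$v), all(edges$bars >= 1),
              all(c(edges$u, edges$v) >= 1), all(c(edges$u, edges$v) <= n))
    uu <- pmin(edges$u, edges$v); vv <- pmax(edges$u, edges$v)
    edges$u <- uu; edges$v <- vv
    edges <- edges[order(edges$u, edges$v), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(n = as.integer(n), edges = edges, bodies = NULL,
                 atoms = NULL), class = "body_bar_graph")
}

#' @export
print.body_bar_graph <- function(x, ...) {
  cat("<body_bar_graph> ", x$n, " bodies, ", nrow(x$edges),
      " edges, ", sum(x$edges$bars), " bars\n", sep = "")
  invisible(x)
}

## --- the (6,6) pebble game -------------------------------------------------

## Internal state: pebbles per vertex and a directed bar-count matrix D
## (D[a, b] = accepted bars oriented a -> b).  Invariant after every move:
## pebbles[v] + sum(D[v, ]) == 6.

new_pebble_state <- function(n) {
  list(n = n, pebbles = rep(6L, n), D = matrix(0L, n, n), rank = 0L)
}

## depth-first search for a free pebble reachable from `start` along
## directed edges, excluding vertices in `avoid` as pebble sources.
## Returns the path (start ... target) or NULL.
find_pebble_path <- function(st, start, avoid) {
  n <- st$n
  seen <- rep(FALSE, n); seen[start] <- TRUE
  parent <- rep(0L, n)
  stack <- c(start)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    targets <- which(st$D[v, ] > 0L & !seen)
    for (w in targets) {
      seen[w] <- TRUE; parent[w] <- v
      if (st$pebbles[w] > 0L && !(w %in% avoid)) {
        path <- w
        while (path[1] != start) path <- c(parent[path[1]], path)
        return(path)
      }
      stack <- c(stack, w)
    }
  }
  NULL
}

## move one pebble from the end of `path` to its start, reversing edges
pull_pebble <- function(st, path) {
  k <- length(path)
  for (t in seq_len(k - 1)) {
    a <- path[t]; b <- path[t + 1]
    st$D[a, b] <- st$D[a, b] - 1L
    st$D[b, a] <- st$D[b, a] + 1L
  }
  st$pebbles[path[k]] <- st$pebbles[path[k]] - 1L
  st$pebbles[path[1]] <- st$pebbles[path[1]] + 1L
  st
}

## gather pebbles on {u, v} until `need` are present (or no more reachable);
## returns the updated state with attr "ok"
gather_pebbles <- function(st, u, v, need = 7L) {
  repeat {
    if (st$pebbles[u] + st$pebbles[v] >= need) break
    path <- find_pebble_path(st, u, c(u, v))
    if (is.null(path)) path <- find_pebble_path(st, v, c(u, v))
    if (is.null(path)) break
    st <- pull_pebble(st, path)
  }
  attr(st, "ok") <- st$pebbles[u] + st$pebbles[v] >= need
  st
}

#' Run the (6,6) pebble game
#'
#' Processes the bars of the multigraph in deterministic order (edges sorted
#' by endpoint ids, bars within an edge consecutively).  A bar (u, v) is
#' accepted iff 7 pebbles can be gathered on {u, v}; accepted bars are
#' oriented and consume one pebble.  The accepted count equals the rank of
#' the 3-D body-bar rigidity matroid of the graph and is independent of
#' processing order.
#'
#' @param graph `body_bar_graph`.
#' @return A `pebble_state`: `pebbles` per body, directed bar matrix `D`,
#'   `rank`, and per-edge accepted counts in `accepted`.
#' @export
pebble_game <- function(graph) {
  st <- new_pebble_state(graph$n)
  ed <- graph$edges
  accepted <- integer(NROW(ed))
  for (e in seq_len(NROW(ed))) {
    u <- ed$u[e]; v <- ed$v[e]
    for (b in seq_len(ed$bars[e])) {
      st <- gather_pebbles(st, u, v, 7L)
      if (!attr(st, "ok")) break
      if (st$pebbles[u] > 0L) {
        st$D[u, v] <- st$D[u, v] + 1L; st$pebbles[u] <- st$pebbles[u] - 1L
      } else {
        st$D[v, u] <- st$D[v, u] + 1L; st$pebbles[v] <- st$pebbles[v] - 1L
      }
      st$rank <- st$rank + 1L
      accepted[e] <- accepted[e] + 1L
    }
  }
  st$accepted <- accepted
  class(st) <- "pebble_state"
  st
}

#' @export
print.pebble_state <- function(x, ...) {
  cat("<pebble_state> ", x$n, " bodies, rank ", x$rank, ", ",
      sum(x$pebbles), " free pebbles\n", sep = "")
  invisible(x)
}

#' Internal degrees of freedom of a body-bar graph
#'
#' For a connected graph this is `6 V - 6 - rank`: the number of independent
#' internal motions beyond the 6 trivial rigid-body motions.  For a
#' disconnected graph the internal DOF are summed per connected component,
#' and the 6 relative DOF per additional component are reported separately
#' in the `"relative_dof"` attribute.
#'
#' @param graph `body_bar_graph`.
#' @param state optional `pebble_state` (computed if missing).
#' @return non-negative integer with attribute `relative_dof`.
#' @export
internal_dof <- function(graph, state = pebble_game(graph)) {
  ncomp <- as.integer(n_weak_components(graph))
  dof <- 6L * graph$n - 6L * ncomp - state$rank
  attr(dof, "relative_dof") <- 6L * (ncomp - 1L)
  dof
}

n_weak_components <- function(graph) {
  g <- igraph::make_empty_graph(graph$n, directed = FALSE)
  if (nrow(graph$edges))
    g <- igraph::add_edges(g, rbind(graph$edges$u, graph$edges$v))
  igraph::components(g)$no
}

#' Rigid components of a body-bar graph
#'
#' Two adjacent bodies lie in a common rigid component iff no 7th pebble can
#' be gathered on them after the game (equivalently: one more bar between
#' them would be redundant, so a (6,6)-tight set already spans them).  Since
#' tight sets sharing a vertex merge into a tight set, this relation is
#' transitive and the components partition the bodies; isolated or flexibly
#' attached bodies form singleton components.
#'
#' @param graph `body_bar_graph`.
#' @param state `pebble_state` from [pebble_game].
#' @return list of integer vectors (body ids), ordered by smallest member.
#' @export
rigid_components <- function(graph, state = pebble_game(graph)) {
  parent <- seq_len(graph$n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; as.integer(x) }
  st <- state
  ed <- graph$edges
  for (e in seq_len(NROW(ed))) {
    ru <- find(ed$u[e]); rv <- find(ed$v[e])
    if (ru == rv) next
    st <- gather_pebbles(st, ed$u[e], ed$v[e], 7L)
    if (!attr(st, "ok")) parent[ru] <- rv
  }
  roots <- vapply(seq_len(graph$n), find, 0L)
  comps <- unname(split(seq_len(graph$n), roots))
  comps <- lapply(comps, as.integer)
  comps[order(vapply(comps, min, 0L))]
}

#' Rigid cluster decomposition of a mechanical model
#'
#' Builds the body-bar graph, runs the pebble game, finds the rigid
#' components and maps them back to atoms.  Atoms shared between bodies
#' through a hinge are counted in every incident cluster (the convention
#' used by the cluster-size tables).
#'
#' @param mm `mech_model`.
#' @param policy [bar_policy].
#' @return A `rigid_decomposition`: `clusters` (list of atom index sets),
#'   `sizes` (atom counts, descending), `internal_dof`, `n_atoms`.
#' @export
rigid_decompose <- function(mm, policy = bar_policy()) {
  graph <- body_bar_graph(mm, policy)
  state <- pebble_game(graph)
  comps <- rigid_components(graph, state)
  clusters <- lapply(comps, function(cs)
    sort(unique(unlist(mm$bodies[cs], use.names = FALSE))))
  sizes <- vapply(clusters, length, 0L)
  o <- order(sizes, decreasing = TRUE)
  structure(list(clusters = clusters[o], sizes = sizes[o],
                 internal_dof = internal_dof(graph, state),
                 n_atoms = nrow(mm$atoms)),
            class = "rigid_decomposition")
}

#' @export
print.rigid_decomposition <- function(x, ...) {
  cat("<rigid_decomposition> ", length(x$clusters), " clusters over ",
      x$n_atoms, " atoms; largest ", if (length(x$sizes)) x$sizes[1] else 0,
      "; internal DOF ", as.integer(x$internal_dof), "\n", sep = "")
  invisible(x)
}

#' Write a decomposition to text files
#'
#' Writes a per-atom cluster assignment TSV (chain, resseq, atom name, unit
#' label, cluster id; atoms in several clusters get one row per cluster)
#' and a JSON size histogram.
#'
#' @param dec `rigid_decomposition`.
#' @param mm the `mech_model` it came from (for atom identities).
#' @param assignment_file,histogram_file output paths (NULL to skip).
#' @return invisibly, the assignment data frame.
#' @export
write_decomposition <- function(dec, mm, assignment_file = NULL,
                                histogram_file = NULL) {
  at <- mm$atoms
  rows <- do.call(rbind, lapply(seq_along(dec$clusters), function(k)
    data.frame(chain = at$chain_id[dec$clusters[[k]]],
               resseq = at$resseq[dec$clusters[[k]]],
               atom = at$name[dec$clusters[[k]]],
               unit = at$unit_label[dec$clusters[[k]]],
               cluster = k, stringsAsFactors = FALSE)))
  if (!is.null(assignment_file))
    utils::write.table(rows, assignment_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(histogram_file)) {
    h <- table(dec$sizes)
    jsonlite::write_json(
      list(sizes = as.integer(names(h)), counts = as.integer(h),
           internal_dof = as.integer(dec$internal_dof)),
      histogram_file, auto_unbox = FALSE)
  }
  invisible(rows)
}

## --- exhaustive sparsity oracle (test support) ------------------------------

#' Matroid-rank oracle for small body-bar graphs
#'
#' Computes the rank of the (6,6)-sparsity matroid directly from its
#' definition: bars are added one at a time, each checked for independence
#' by verifying `bars(S) <= 6|S| - 6` over every vertex subset S with
#' |S| >= 2.  Because the independent sets form a matroid, greedy insertion
#' attains the maximum independent subset; as a safeguard against
#' implementation error the greedy pass is repeated over `shuffles` random
#' bar orders (seeded) and the maximum is returned.  Intended as an
#' independent check of [pebble_game] on small graphs only.
#'
#' @param graph `body_bar_graph` with at most 6 vertices and 20 bars.
#' @param shuffles number of random insertion orders.
#' @param seed RNG seed for the shuffles.
#' @return integer rank.
#' @export
oracle_rank <- function(graph, shuffles = 20L, seed = 1L) {
  V <- graph$n
  bars <- graph$edges[rep(seq_len(NROW(graph$edges)), graph$edges$bars),
                      c("u", "v"), drop = FALSE]
  if (V > 6 || nrow(bars) > 20)
    stop("oracle_rank: refusing graphs beyond V <= 6, bars <= 20")
  if (V < 2 || nrow(bars) == 0) return(0L)
  subsets <- which(vapply(seq_len(2^V) - 1L, function(m)
    sum(bitwAnd(m, 2^(0:(V - 1))) > 0) >= 2, TRUE))
  masks <- (seq_len(2^V) - 1L)[subsets]
  cap <- vapply(masks, function(m)
    6L * sum(bitwAnd(m, 2^(0:(V - 1))) > 0) - 6L, 0L)
  in_subset <- function(m, a) bitwAnd(m, bitwShiftL(1L, a - 1L)) > 0
  bar_masks <- lapply(seq_len(nrow(bars)), function(b)
    which(vapply(masks, function(m)
      in_subset(m, bars$u[b]) && in_subset(m, bars$v[b]), TRUE)))
  run <- function(ord) {
    cnt <- integer(length(masks)); r <- 0L
    for (b in ord) {
      sel <- bar_masks[[b]]
      if (all(cnt[sel] + 1L <= cap[sel])) {
        cnt[sel] <- cnt[sel] + 1L; r <- r + 1L
      }
    }
    r
  }
  best <- run(seq_len(nrow(bars)))
  if (shuffles > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    for (s in seq_len(shuffles))
      best <- max(best, run(sample(nrow(bars))))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  best
}
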