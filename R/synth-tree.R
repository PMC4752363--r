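#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Forward simulation of a constant-rate pure-birth process: while `k`
#' lineages exist the waiting time to the next speciation is exponential
#' with rate `k * birth_rate`, and the lineage that splits is chosen
#' uniformly. The process is observed through the epoch during which
#' `n_tips` lineages exist (i.e. up to, but not including, the next
#' speciation), so all pendant edges are strictly positive and the tree is
#' ultrametric. The initial single-lineage wait is retained as the stem
#' (`root.edge`); root-to-tip depths measured from the root exclude it.
#'
#' The expected origin-to-tip height (stem included) is
#' `sum(1 / (birth_rate * (1:n_tips)))`.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth_rate Per-lineage speciation rate (> 0), per unit branch
#'   length.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   trees. The caller's RNG state is left untouched.
#' @return An [ape] `phylo` object with unique tip labels `t1..tn`, strictly
#'   positive branch lengths and a `root.edge` stem.
#' @examples
#' tr <- simulate_yule_tree(10, birth_rate = 1, seed = 1)
#' ape::is.ultrametric(tr)
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (!is.numeric(n_tips) || length(n_tips) != 1L || !is.finite(n_tips) ||
      n_tips < 2 || n_tips %% 1 != 0) {
    stop("`n_tips` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(birth_rate) || length(birth_rate) != 1L || birth_rate <= 0) {
    stop("`birth_rate` must be a single positive rate", call. = FALSE)
  }
  n <- as.integer(n_tips)
  with_seed(seed, {
    waits <- rexp(n, rate = birth_rate * seq_len(n))
    picks <- vapply(seq_len(n - 1L),
                    function(k) if (k == 1L) 1L else sample.int(k, 1L),
                    integer(1))
    build_yule_phylo(n, waits, picks)
  })
}

# Assemble the phylo object from the event times and split choices.
# Pending lineages are open edges (parent node, start time); at the j-th
# split the chosen pending edge is closed by internal node n+j, which opens
# two new pending edges. Remaining pending edges become tips at the end of
# the n-lineage epoch.
build_yule_phylo <- function(n, waits, picks) {
  times <- cumsum(waits)          # times[j] = j-th speciation (j < n)
  t_end <- times[n]               # end of observation window
  n_edge <- 2L * n - 2L
  edge <- matrix(0L, n_edge, 2L)
  elen <- numeric(n_edge)
  ne <- 0L
  # pending edges: parent node id (0 = origin) and start time
  p_par <- c(0L); p_t0 <- c(0)
  for (j in seq_len(n - 1L)) {
    i <- picks[j]
    node <- n + j                      # root is n + 1
    if (p_par[i] != 0L) {              # stem closure is not a tree edge
      ne <- ne + 1L
      edge[ne, ] <- c(p_par[i], node)
      elen[ne] <- times[j] - p_t0[i]
    }
    p_par <- c(p_par[-i], node, node)
    p_t0 <- c(p_t0[-i], times[j], times[j])
  }
  for (i in seq_len(n)) {              # close pendant edges as tips
    ne <- ne + 1L
    edge[ne, ] <- c(p_par[i], i)
    elen[ne] <- t_end - p_t0[i]
  }
  tr <- list(edge = edge, edge.length = elen,
             tip.label = paste0("t", seq_len(n)),
             Nnode = n - 1L, root.edge = waits[1L])
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Height of a rooted tree
#'
#' Maximum root-to-tip path length; optionally including the stem
#' (`root.edge`) so that for simulated pure-birth trees the value is the
#' full origin-to-present time.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param include_stem Add `root.edge` (if present) to the depth.
#' @return Numeric scalar.
#' @export
tree_height <- function(tree, include_stem = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  h <- max(ape::node.depth.edgelength(tree))
  if (include_stem && !is.null(tree$root.edge)) h <- h + tree$root.edge
  h
}
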