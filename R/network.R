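#' Build the weighted semantic network from a co-occurrence table
#'
#' Nodes are the seed lemmas plus every lemma whose seed co-occurrence
#' frequency reaches `min_node_freq`; node size is that frequency (seed
#' lemmas get size 1, as they appear in every seed sentence by
#' construction). Edges connect lemma pairs whose sentence co-occurrence
#' count reaches `min_edge_count`, weighted by that count; seed-lemma edges
#' carry the count of seed sentences containing both that seed and the
#' lemma. Non-seed nodes left without any edge are dropped.
#'
#' @param table A `cooc_table` from [compute_frequencies()].
#' @param lexicon A [seed_lexicon()].
#' @param config A [run_config()] supplying `min_node_freq` and
#'   `min_edge_count`.
#' @return An object of class `semnet`: list with `nodes` (data.frame
#'   `lemma`, `size`, `is_seed`, bytewise-sorted) and `edges` (data.frame
#'   `from`, `to`, `weight` with `from` < `to` bytewise, sorted).
#' @export
build_network <- function(table, lexicon = seed_lexicon(),
                          config = run_config()) {
  stopifnot(inherits(table, "cooc_table"))
  seeds <- intersect(lexicon$seed_lemmas, names(table$lemma_totals))
  if (!length(seeds)) seeds <- lexicon$seed_lemmas
  cand <- names(table$freq)[table$freq >= config$min_node_freq]
  node_set <- unique(c(seeds, cand))

  e <- table$pair_counts
  keep <- e$count >= config$min_edge_count &
    e$lemma_a %in% node_set & e$lemma_b %in% node_set
  e <- e[keep, , drop = FALSE]
  if (nrow(e) == 0L)
    stage_stop("network", "empty network: no edge meets min_edge_count = ",
               config$min_edge_count)

  touched <- unique(c(e$lemma_a, e$lemma_b))
  node_set <- node_set[node_set %in% touched | node_set %in% seeds]

  size <- ifelse(node_set %in% seeds, 1.0, unname(table$freq[node_set]))
  nodes <- data.frame(lemma = node_set, size = size,
                      is_seed = node_set %in% seeds,
                      stringsAsFactors = FALSE)
  nodes <- nodes[lex_order(nodes$lemma), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- data.frame(from = e$lemma_a, to = e$lemma_b,
                      weight = as.numeric(e$count),
                      stringsAsFactors = FALSE)
  edges <- edges[lex_order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "semnet")
}

#' Construct a semantic network directly from node and edge tables
#'
#' Mostly useful for tests and small worked examples; [build_network()] is
#' the production constructor.
#'
#' @param nodes data.frame with at least `lemma`; optional `size`
#'   (default 1) and `is_seed` (default FALSE).
#' @param edges data.frame with `from`, `to`, `weight` (> 0); self-loops
#'   are not allowed.
#' @return A `semnet`.
#' @export
semnet <- function(nodes, edges) {
  if (is.character(nodes))
    nodes <- data.frame(lemma = nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$size)) nodes$size <- 1.0
  if (is.null(nodes$is_seed)) nodes$is_seed <- FALSE
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  if (any(edges$from == edges$to))
    stop("self-loops are not allowed", call. = FALSE)
  if (any(edges$weight <= 0))
    stop("edge weights must be positive", call. = FALSE)
  miss <- setdiff(unique(c(edges$from, edges$to)), nodes$lemma)
  if (length(miss))
    stop("edge endpoint(s) not in nodes: ", paste(miss, collapse = ", "),
         call. = FALSE)
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  nodes <- nodes[lex_order(nodes$lemma), c("lemma", "size", "is_seed"),
                 drop = FALSE]
  edges <- edges[lex_order(edges$from, edges$to),
                 c("from", "to", "weight"), drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "semnet")
}

#' @export
print.semnet <- function(x, ...) {
  cat(sprintf("<semnet> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_membership <- function(partition, network) {
  m <- if (inherits(partition, "semnet_partition")) partition$membership
       else partition
  miss <- setdiff(network$nodes$lemma, names(m))
  if (length(miss))
    stop("node(s) missing from partition: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m[network$nodes$lemma]
}

#' Resolution-scaled modularity of a partition
#'
#' Computes the generalized Newman-Girvan modularity
#' \deqn{Q_\gamma = \sum_c \left[\frac{W_c}{W} -
#'   \gamma\left(\frac{S_c}{2W}\right)^2\right]}
#' where \eqn{W} is the total edge weight, \eqn{W_c} the weight inside
#' community \eqn{c}, \eqn{S_c} the summed weighted degree of its nodes and
#' \eqn{\gamma} the resolution parameter scaling the configuration-model
#' null term. At \eqn{\gamma = 1} this is ordinary weighted modularity; a
#' single all-in-one community scores \eqn{1 - \gamma} on any graph.
#'
#' @param network A `semnet`.
#' @param partition A `semnet_partition` or a named community-id vector
#'   covering every node.
#' @param resolution Gamma (> 0); defaults to the partition's own
#'   resolution, else 1.
#' @param weighted If `FALSE`, all edge weights are treated as 1.
#' @return The modularity value (a number, at most 1).
#' @export
modularity_score <- function(network, partition, resolution = NULL,
                             weighted = TRUE) {
  stopifnot(inherits(network, "semnet"))
  if (is.null(resolution))
    resolution <- if (inherits(partition, "semnet_partition"))
      partition$resolution else 1
  m <- as_membership(partition, network)
  w <- if (weighted) network$edges$weight else rep(1, nrow(network$edges))
  W <- sum(w)
  if (W == 0) return(0)
  cf <- m[network$edges$from]; ct <- m[network$edges$to]
  W_c <- tapply(w[cf == ct], cf[cf == ct], sum)
  deg <- tapply(c(w, w), c(network$edges$from, network$edges$to), sum)
  deg <- deg[network$nodes$lemma]
  deg[is.na(deg)] <- 0
  S_c <- tapply(deg, m, sum)
  sum(W_c) / W - resolution * sum((S_c / (2 * W))^2)
}

# ---- Louvain ----------------------------------------------------------------

# One greedy local-move phase on an aggregated graph.
# adj: list of data.frames (nbr index, weight); deg: weighted degrees
# (self-loops already counted twice); W: total weight. Returns community ids.
louvain_local <- function(adj, deg, W, gamma, order) {
  n <- length(adj)
  comm <- seq_len(n)
  S <- deg  # community degree sums
  repeat {
    improved <- FALSE
    for (i in order) {
      d <- comm[i]
      nb <- adj[[i]]
      if (!nrow(nb)) next
      # weight from i to each neighbouring community
      k_ic <- tapply(nb$weight, comm[nb$nbr], sum)
      cand <- as.integer(names(k_ic))
      if (!(d %in% cand)) { cand <- c(cand, d); k_ic <- c(k_ic, 0) }
      S_excl <- S[cand] - ifelse(cand == d, deg[i], 0)
      gain <- k_ic / W - gamma * deg[i] * S_excl / (2 * W^2)
      cur <- which(cand == d)
      best <- max(gain)
      # tie rule: keep the current community on ties, else lowest id
      if (best - gain[cur] <= 1e-12) next
      winners <- cand[gain >= best - 1e-12]
      target <- min(winners)
      if (target == d) next
      comm[i] <- target
      S[d] <- S[d] - deg[i]
      S[target] <- S[target] + deg[i]
      improved <- TRUE
    }
    if (!improved) break
  }
  comm
}

#' Louvain community detection with a resolution parameter
#'
#' A from-scratch two-phase Louvain optimizer of the resolution-scaled
#' modularity [modularity_score()]: greedy local moves over nodes in a
#' seed-shuffled order until no single move improves \eqn{Q_\gamma}, then
#' aggregation of communities into super-nodes, repeated until the partition
#' stabilizes. Equal-gain moves keep the current community, otherwise take
#' the lowest community id, so the result is fully determined by
#' `config$rng_seed`.
#'
#' @param network A non-empty `semnet`.
#' @param config A [run_config()] supplying `resolution` (gamma) and
#'   `rng_seed`.
#' @param weighted If `FALSE`, optimize unweighted modularity (every edge
#'   counts 1) — some network tools report modularity classes on the
#'   binarized graph.
#' @return An object of class `semnet_partition`: list with `membership`
#'   (named integer vector, dense community ids from 0), `resolution`,
#'   `modularity` (the attained \eqn{Q_\gamma}) and `rng_seed`.
#' @export
louvain <- function(network, config = run_config(), weighted = TRUE) {
  stopifnot(inherits(network, "semnet"))
  if (nrow(network$nodes) == 0L)
    stage_stop("louvain", "network has no nodes")
  gamma <- config$resolution
  lemmas <- network$nodes$lemma
  n <- length(lemmas)
  ef <- match(network$edges$from, lemmas)
  et <- match(network$edges$to, lemmas)
  ew <- if (weighted) network$edges$weight else rep(1, nrow(network$edges))

  # current aggregated graph
  a_from <- ef; a_to <- et; a_w <- ew
  a_self <- numeric(n)
  node_map <- seq_len(n)  # original node -> aggregate node
  n_agg <- n
  level <- 0L

  repeat {
    level <- level + 1L
    adj <- rep(list(data.frame(nbr = integer(0), weight = numeric(0))), n_agg)
    if (length(a_from)) {
      inc_node <- c(a_from, a_to)
      inc_nbr <- c(a_to, a_from)
      inc_w <- c(a_w, a_w)
      sp <- split(seq_along(inc_node), inc_node)
      for (k in names(sp)) {
        idx <- sp[[k]]
        adj[[as.integer(k)]] <- data.frame(nbr = inc_nbr[idx],
                                           weight = inc_w[idx])
      }
    }
    deg <- numeric(n_agg)
    for (i in seq_len(n_agg)) deg[i] <- sum(adj[[i]]$weight) + 2 * a_self[i]
    W <- sum(a_w) + sum(a_self)
    ord <- with_seed(config$rng_seed + level, sample.int(n_agg))

    comm <- louvain_local(adj, deg, W, gamma, ord)
    ids <- sort(unique(comm))
    if (length(ids) == n_agg) break  # no merge happened: stable

    relabel <- match(comm, ids)
    node_map <- relabel[node_map]
    # aggregate: intra weights + old self-loops become new self-loops
    n_new <- length(ids)
    self_new <- numeric(n_new)
    for (i in seq_len(n_agg))
      self_new[relabel[i]] <- self_new[relabel[i]] + a_self[i]
    if (length(a_from)) {
      cf <- relabel[a_from]; ct <- relabel[a_to]
      intra <- cf == ct
      if (any(intra)) {
        add <- tapply(a_w[intra], cf[intra], sum)
        self_new[as.integer(names(add))] <-
          self_new[as.integer(names(add))] + add
      }
      lo <- pmin(cf[!intra], ct[!intra]); hi <- pmax(cf[!intra], ct[!intra])
      if (length(lo)) {
        key <- paste0(lo, "_", hi)
        wagg <- tapply(a_w[!intra], key, sum)
        parts <- strsplit(names(wagg), "_", fixed = TRUE)
        a_from <- as.integer(vapply(parts, `[`, character(1), 1L))
        a_to <- as.integer(vapply(parts, `[`, character(1), 2L))
        a_w <- as.numeric(wagg)
      } else {
        a_from <- integer(0); a_to <- integer(0); a_w <- numeric(0)
      }
    }
    a_self <- self_new
    n_agg <- n_new
    if (n_agg == 1L) break
  }

  # dense ids from 0, numbered by first appearance over bytewise node order
  first <- !duplicated(node_map)
  dense <- stats::setNames(seq_along(node_map[first]) - 1L,
                           node_map[first])
  membership <- stats::setNames(dense[as.character(node_map)], lemmas)
  part <- structure(
    list(membership = membership,
         resolution = gamma,
         modularity = NA_real_,
         rng_seed = config$rng_seed),
    class = "semnet_partition"
  )
  part$modularity <- modularity_score(network, part, gamma,
                                      weighted = weighted)
  part
}

#' @export
print.semnet_partition <- function(x, ...) {
  cat(sprintf("<semnet_partition> %d nodes, %d communities, gamma = %g, Q = %.4f\n",
              length(x$membership), length(unique(x$membership)),
              x$resolution, x$modularity))
  invisible(x)
}

#' Rank modularity classes by size
#'
#' Orders the detected clusters the way a thematic reading proceeds: largest
#' first. Ties on node count fall back to total node size (summed
#' frequencies), then to the bytewise-smallest member lemma.
#'
#' @param partition A `semnet_partition` covering `network`.
#' @param network A `semnet`.
#' @return data.frame with columns `cluster_id`, `rank`, `n_nodes`,
#'   `total_size`, `members` (lemmas sorted by node size descending, ties
#'   lexicographic, separated by "; ").
#' @export
rank_clusters <- function(partition, network) {
  m <- as_membership(partition, network)
  nd <- network$nodes
  stats_by <- lapply(split(seq_len(nrow(nd)), m[nd$lemma]), function(idx) {
    sub <- nd[idx, , drop = FALSE]
    sub <- sub[lex_order(-sub$size, sub$lemma), , drop = FALSE]
    list(n = nrow(sub), total = sum(sub$size),
         first = sub$lemma[lex_order(sub$lemma)][1L],
         members = paste(sub$lemma, collapse = "; "))
  })
  d <- data.frame(
    cluster_id = as.integer(names(stats_by)),
    n_nodes = vapply(stats_by, `[[`, numeric(1), "n"),
    total_size = vapply(stats_by, `[[`, numeric(1), "total"),
    first_lemma = vapply(stats_by, `[[`, character(1), "first"),
    members = vapply(stats_by, `[[`, character(1), "members"),
    stringsAsFactors = FALSE
  )
  d <- d[lex_order(-d$n_nodes, -d$total_size, d$first_lemma), , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  rownames(d) <- NULL
  d[c("cluster_id", "rank", "n_nodes", "total_size", "members")]
}
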