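# Median-joining haplotype networks.
#
# Distances are mutational steps on the recoded character matrix, so a
# multi-base indel event counts as a single step.  The network stage follows
# the Bandelt median-joining scheme: a minimum-spanning network (keeping all
# links that tie the partition-merging minimum, within a tolerance epsilon),
# augmented with quasi-median (hypothetical, unsampled) haplotypes wherever
# they reduce the cost of connecting the observed ones, iterated to a
# fixpoint, with obsolete medians removed.

#' Mutational distance between two state vectors
#'
#' Counts characters with differing non-missing states; an indel character
#' contributes at most 1 regardless of event length, and `N` never
#' contributes.
#'
#' @param x,y State vectors over the same character schema.
#' @return Non-negative integer.
#' @export
mutation_distance <- function(x, y) {
  if (length(x) != length(y)) {
    abort("state vectors differ in length", class = "hybridID_schema_error")
  }
  sum(x != y & x != "N" & y != "N")
}

dist_matrix <- function(states) {
  n <- length(states)
  d <- matrix(0L, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- mutation_distance(states[[i]], states[[j]])
      }
    }
  }
  d
}

mst_cost <- function(d) {
  n <- nrow(d)
  if (n <= 1) return(0)
  # Prim
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  cost <- 0
  for (step in seq_len(n - 1)) {
    j <- which(!in_tree)[which.min(best[!in_tree])]
    cost <- cost + best[j]
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  cost
}

# Epsilon-relaxed minimum spanning network: an edge (u,v) is kept iff its
# weight is within epsilon of the weight class at which the components of u
# and v first become connected (Kruskal processed by whole weight classes).
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n <= 1) return(tibble(from = integer(), to = integer(), weight = integer()))
  cw <- matrix(Inf, n, n)
  comp <- seq_len(n)
  for (w in sort(unique(d[upper.tri(d)]))) {
    adj <- d <= w
    # connected components using all edges of weight <= w
    newcomp <- seq_len(n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, j]) {
          a <- newcomp[i]; b <- newcomp[j]
          if (a != b) newcomp[newcomp == b] <- a
        }
      }
    }
    newly <- outer(newcomp, newcomp, "==") & !outer(comp, comp, "==")
    cw[newly & is.infinite(cw)] <- w
    comp <- newcomp
    if (length(unique(comp)) == 1 && all(is.finite(cw[upper.tri(cw)]))) break
  }
  keep <- which(upper.tri(d) & d <= cw + epsilon, arr.ind = TRUE)
  tibble(from = keep[, 1], to = keep[, 2], weight = d[keep])
}

# Quasi-medians of a node triple: per character the majority state; where the
# three states are all distinct (or tied after dropping N) the candidate
# splits into every optimal state.  Returns a list of state vectors.
quasi_medians <- function(a, b, c, max_split = 729) {
  maj <- ifelse((a == b | a == c) & a != "N", a,
                ifelse(b == c & b != "N", b, NA))
  pending <- which(is.na(maj))
  if (length(pending) == 0) return(list(maj))
  per_char <- lapply(pending, function(k) {
    s <- c(a[k], b[k], c[k])
    s <- s[s != "N"]
    if (length(s) == 0) return("N")
    u <- unique(s)
    if (length(u) == 1) return(u)
    cnt <- vapply(u, function(x) sum(s == x), integer(1))
    sort(u[cnt == max(cnt)])
  })
  lens <- lengths(per_char)
  if (prod(lens) > max_split) return(list())
  maj[pending[lens == 1]] <- unlist(per_char[lens == 1])
  multi <- pending[lens > 1]
  if (length(multi) == 0) return(list(maj))
  grid <- expand.grid(per_char[lens > 1], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    v <- maj
    v[multi] <- as.character(grid[i, ])
    v
  })
}

#' Build a median-joining haplotype network
#'
#' @param panel A `haplotype_panel` (typically the two species' panels merged
#'   with [combine_panels()], or one species for a per-species subnetwork).
#' @param epsilon Non-negative integer relaxation of the minimum-spanning
#'   criterion (0 reproduces the strict minimum spanning network).
#' @param max_medians Cap on the number of median vectors admitted (guards
#'   the closure on degenerate inputs; never reached on star-like panels).
#' @return An `mj_network`: `$nodes` (name, species, count, is_median, states
#'   list-column), `$edges` (from, to, weight), `$cost` (minimum spanning
#'   cost over all retained nodes, i.e. total mutational steps needed to
#'   connect the network).
#' @details Deterministic: observed haplotypes are processed in name order and
#'   candidate medians in lexicographic state order; the best-improving median
#'   is added at each round until no candidate reduces the connection cost.
#'   Median (hypothetical) nodes that end with degree <= 1 are removed.
#'   Haplotype frequencies do not influence topology; counts only annotate
#'   node size.
#' @export
median_joining <- function(panel, epsilon = 0, max_medians = 64L) {
  if (is.null(panel$haplotypes) || nrow(panel$haplotypes) == 0) {
    abort("empty haplotype panel", class = "hybridID_data_error")
  }
  obs <- panel$haplotypes[order(panel$haplotypes$name), ]
  nodes <- tibble(
    name = obs$name, species = obs$species, count = obs$total,
    is_median = FALSE, states = obs$states
  )
  n_obs <- nrow(nodes)
  med_i <- 0L
  max_nodes <- n_obs + max_medians
  repeat {
    d <- dist_matrix(nodes$states)
    base_cost <- mst_cost(d)
    keys <- vapply(nodes$states, hap_key, character(1))
    # candidate medians from every node triple, lexicographic order
    cand <- list()
    if (nrow(nodes) >= 3) {
      for (tri in utils::combn(nrow(nodes), 3, simplify = FALSE)) {
        for (qm in quasi_medians(nodes$states[[tri[1]]], nodes$states[[tri[2]]],
                                 nodes$states[[tri[3]]])) {
          k <- hap_key(qm)
          if (!(k %in% keys) && is.null(cand[[k]])) cand[[k]] <- qm
        }
      }
    }
    if (length(cand) == 0 || nrow(nodes) >= max_nodes) break
    cand <- cand[order(names(cand))]
    gains <- vapply(cand, function(qm) {
      dd <- vapply(nodes$states, mutation_distance, integer(1), y = qm)
      d2 <- rbind(cbind(d, dd), c(dd, 0L))
      base_cost - mst_cost(d2)
    }, numeric(1))
    add_node <- function(qm) {
      med_i <<- med_i + 1L
      nodes <<- dplyr::bind_rows(nodes, tibble(
        name = sprintf("mv%d", med_i), species = "median", count = 0L,
        is_median = TRUE, states = list(qm)
      ))
    }
    if (max(gains) > 0) {
      # strict improvement: take the first (lexicographic) maximal gain
      add_node(cand[[which.max(gains)]])
      next
    }
    # No single candidate improves the cost.  Some optima need two medians
    # that only pay off jointly (each splits a path the other reroutes), so
    # search candidate pairs; deterministic lexicographic order, bounded to
    # keep degenerate inputs tractable.
    if (length(cand) > 100 || nrow(nodes) + 2L > max_nodes) break
    ddc <- lapply(cand, function(qm) {
      vapply(nodes$states, mutation_distance, integer(1), y = qm)
    })
    best2 <- 0
    best_pair <- NULL
    for (i in seq_along(cand)[-length(cand)]) {
      for (j in (i + 1):length(cand)) {
        dij <- mutation_distance(cand[[i]], cand[[j]])
        d2 <- rbind(cbind(d, ddc[[i]], ddc[[j]]),
                    c(ddc[[i]], 0L, dij),
                    c(ddc[[j]], dij, 0L))
        g2 <- base_cost - mst_cost(d2)
        if (g2 > best2) {
          best2 <- g2
          best_pair <- c(i, j)
        }
      }
    }
    if (is.null(best_pair)) break
    add_node(cand[[best_pair[1]]])
    add_node(cand[[best_pair[2]]])
  }
  # backward elimination: drop any median whose removal does not increase the
  # connection cost (keeps the median set minimal and deterministic)
  repeat {
    cur <- mst_cost(dist_matrix(nodes$states))
    meds <- which(nodes$is_median)
    if (length(meds) == 0) break
    meds <- meds[order(vapply(nodes$states[meds], hap_key, character(1)))]
    removed <- FALSE
    for (m in meds) {
      if (mst_cost(dist_matrix(nodes$states[-m])) <= cur) {
        nodes <- nodes[-m, , drop = FALSE]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  # final network + obsolete-median cleanup
  repeat {
    d <- dist_matrix(nodes$states)
    edges <- msn_edges(d, epsilon)
    deg <- tabulate(c(edges$from, edges$to), nbins = nrow(nodes))
    drop <- which(nodes$is_median & deg <= 1)
    if (length(drop) == 0) break
    nodes <- nodes[-drop, , drop = FALSE]
  }
  edges$from <- nodes$name[edges$from]
  edges$to <- nodes$name[edges$to]
  structure(
    list(nodes = nodes, edges = edges,
         cost = mst_cost(dist_matrix(nodes$states)),
         characters = panel$characters, locus = panel$locus,
         epsilon = epsilon),
    class = "mj_network"
  )
}

#' @export
print.mj_network <- function(x, ...) {
  cat(sprintf("<mj_network> locus %s: %d nodes (%d median), %d edges, cost %d (epsilon %d)\n",
              x$locus, nrow(x$nodes), sum(x$nodes$is_median),
              nrow(x$edges), x$cost, x$epsilon))
  invisible(x)
}

#' @export
tidy.mj_network <- function(x, ...) as_tibble(x$edges)

#' @export
glance.mj_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_median = sum(x$nodes$is_median),
         n_edges = nrow(x$edges), cost = x$cost, epsilon = x$epsilon)
}

#' Convert an mj_network to an igraph graph
#' @param net An `mj_network`.
#' @return An igraph object with vertex attributes `name`, `species`,
#'   `count`, `is_median` and edge attribute `weight`.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges,
    directed = FALSE,
    vertices = net$nodes[, c("name", "species", "count", "is_median")]
  )
}

#' Export a haplotype network
#'
#' @param net An `mj_network`.
#' @param path Output file path.
#' @param format `edge_tsv` (edge list TSV, plus a `<path>.nodes.tsv`
#'   companion with node attributes), `graphml`, or `dot`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edge_tsv", "graphml", "dot")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(sprintf("unknown network format '%s'", format[1]),
                                               class = "hybridID_usage_error"))
  if (format == "edge_tsv") {
    write_tsv_stable(net$edges, path)
    write_tsv_stable(net$nodes[, c("name", "species", "count", "is_median")],
                     paste0(path, ".nodes.tsv"))
  } else {
    g <- as_igraph(net)
    igraph::V(g)$is_median <- as.integer(igraph::V(g)$is_median)
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}

#' Read back a network written as graphml
#' @param path A graphml file from [export_network()].
#' @return An igraph object.
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
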