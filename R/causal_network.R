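# Causal contextualization of a signed prior-knowledge network (PKN):
# find the parsimonious signed sub-network connecting candidate
# perturbation nodes (kinases) to measured TF activities, then call
# consensus targets via reciprocal pairwise contrasts and a three-way
# intersection.
#
# Objective (minimized):
#   sum_m weight_m * 1[state(tf_m) != sign_m]      (measurement mismatch)
#   + beta * #{nodes with state != 0}              (node parsimony)
#   - lambda * sum_v |score_v| * 1[state(v) == sign(score_v)]  (pathway reward)
# subject to: every active non-candidate node has at least one active
# incoming edge whose source state times edge sign equals its own state,
# and the active support structure is acyclic (equivalently: all active
# nodes are reachable from active candidates through sign-consistent
# edges, added one at a time).

#' Preprocess a raw signed network into a PKN
#'
#' Edges confirmed by fewer than `min_sources` independent sources are
#' removed; entries annotated with both signs (sign token `"both"` or `0`)
#' are split into a +1 and a -1 edge; self-loops are dropped (unless
#' allowed). Counts are logged.
#'
#' @param raw data.frame(source, sign, target, n_sources); sign may be
#'   +/-1, `"activation"`, `"inhibition"`, `"both"` or `0`
#' @param min_sources minimum evidence count (default 3)
#' @param allow_self_loops keep self-loops (default FALSE)
#' @return data.frame(source, sign, target, n_sources) with sign in
#'   {+1, -1}
#' @export
preprocess_pkn <- function(raw, min_sources = 3L, allow_self_loops = FALSE) {
  sgn <- as.character(raw$sign)
  map <- c("1" = 1L, "+1" = 1L, "activation" = 1L,
           "-1" = -1L, "inhibition" = -1L, "0" = 0L, "both" = 0L)
  s <- map[sgn]
  if (anyNA(s)) stopf("unknown sign token '%s'", sgn[which(is.na(s))[1]])
  raw$sign <- as.integer(s)
  dual <- raw$sign == 0L
  if (any(dual)) {
    sc_log("preprocess_pkn: splitting %d dual-signed interaction(s)", sum(dual))
    plus <- raw[dual, , drop = FALSE]; plus$sign <- 1L
    minus <- raw[dual, , drop = FALSE]; minus$sign <- -1L
    raw <- rbind(raw[!dual, , drop = FALSE], plus, minus)
  }
  low <- raw$n_sources < min_sources
  if (any(low)) {
    sc_log("preprocess_pkn: removing %d edge(s) with < %d sources", sum(low),
           min_sources)
  }
  raw <- raw[!low, , drop = FALSE]
  if (!allow_self_loops) {
    self <- raw$source == raw$target
    if (any(self)) sc_log("preprocess_pkn: dropping %d self-loop(s)", sum(self))
    raw <- raw[!self, , drop = FALSE]
  }
  raw <- raw[!duplicated(raw[, c("source", "sign", "target")]), , drop = FALSE]
  if (!nrow(raw)) stopf("empty network after preprocessing")
  rownames(raw) <- NULL
  raw
}

#' Weighted footprint pathway scores
#'
#' z = sum(w_g stat_g) / sqrt(sum(w_g^2)) per pathway over the genes shared
#' with the signature; standard normal under a random-signature null.
#' Pathways with no overlap give NA.
#'
#' @param signature named numeric vector of gene statistics
#' @param footprint pathway x gene weight matrix
#' @return named numeric vector of pathway z-scores
#' @export
pathway_scores <- function(signature, footprint) {
  shared <- intersect(colnames(footprint), names(signature))
  if (!length(shared)) stopf("footprint genes do not overlap the signature")
  vapply(rownames(footprint), function(pw) {
    w <- footprint[pw, shared]
    use <- w != 0
    if (!any(use)) return(NA_real_)
    sum(w[use] * signature[shared][use]) / sqrt(sum(w[use]^2))
  }, numeric(1))
}

# ---- internal solver machinery ------------------------------------------

# Grow the active set from active candidates through sign-consistent edges.
# Returns NULL if some active node cannot be supported (infeasible), else
# the supporting edge rows in discovery order (guaranteed acyclic).
support_structure <- function(state, edges, candidates) {
  active <- names(state)[state != 0L]
  added <- intersect(active, candidates)
  pending <- setdiff(active, added)
  sel <- integer(0)
  usable <- edges$source %in% active & edges$target %in% active &
    state[edges$source] * edges$sign == state[edges$target]
  repeat {
    if (!length(pending)) return(edges[sel, , drop = FALSE])
    hit <- which(usable & edges$source %in% added & edges$target %in% pending)
    if (!length(hit)) return(NULL)
    sel <- c(sel, hit)
    added <- union(added, edges$target[hit])
    pending <- setdiff(pending, edges$target[hit])
  }
}

solution_objective <- function(state, meas, beta, lambda, scores) {
  mism <- if (nrow(meas)) {
    st <- state[meas$tf]
    st[is.na(st)] <- 0L
    sum(meas$weight * (st != meas$sign))
  } else 0
  size <- beta * sum(state != 0L)
  reward <- 0
  if (!is.null(scores) && length(scores)) {
    sn <- intersect(names(scores), names(state))
    reward <- lambda * sum(abs(scores[sn]) *
                             (state[sn] == sign(scores[sn]) & state[sn] != 0L))
  }
  list(objective = mism + size - reward, mismatch = mism, size = size,
       reward = reward)
}

# Kahn topological sort; returns the order, or NULL if the graph is cyclic.
topo_order <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges$target)
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  queue <- sort(nodes[indeg == 0L])
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (w in edges$target[edges$source == v]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- sort(c(queue, w))
    }
  }
  if (length(out) == length(nodes)) out else NULL
}

is_dag <- function(nodes, edges) !is.null(topo_order(nodes, edges))

# Exhaustive enumeration over all 3^n states of one component. For DAG
# components the local support check is vectorized over the full state
# table; otherwise states are enumerated with the constructive check.
solve_component_exhaustive <- function(nodes, edges, meas, candidates, beta,
                                       lambda, scores, max_nodes = 15L) {
  n <- length(nodes)
  n_free <- n - sum(nodes %in% meas$tf)
  if (n_free > max_nodes) {
    stopf("exhaustive solver refuses components with > %d non-measured nodes",
          max_nodes)
  }
  S <- as.matrix(expand.grid(rep(list(c(0L, 1L, -1L)), n),
                             KEEP.OUT.ATTRS = FALSE))
  colnames(S) <- nodes
  cand_here <- intersect(nodes, candidates)
  if (is_dag(nodes, edges)) {
    feas <- rep(TRUE, nrow(S))
    for (v in setdiff(nodes, cand_here)) {
      sv <- S[, v]
      ok <- sv == 0L
      ine <- which(edges$target == v)
      for (e in ine) {
        u <- edges$source[e]
        ok <- ok | (S[, u] != 0L & S[, u] * edges$sign[e] == sv)
      }
      feas <- feas & ok
    }
  } else {
    feas <- vapply(seq_len(nrow(S)), function(i) {
      st <- stats::setNames(S[i, ], nodes)
      !is.null(support_structure(st, edges, cand_here))
    }, logical(1))
  }
  obj <- rep(0, nrow(S))
  if (nrow(meas)) {
    for (r in seq_len(nrow(meas))) {
      if (meas$tf[r] %in% nodes) {
        obj <- obj + meas$weight[r] * (S[, meas$tf[r]] != meas$sign[r])
      }
    }
  }
  obj <- obj + beta * rowSums(S != 0L)
  if (!is.null(scores)) {
    for (v in intersect(names(scores), nodes)) {
      obj <- obj - lambda * abs(scores[v]) *
        (S[, v] == sign(scores[v]) & S[, v] != 0L)
    }
  }
  obj[!feas] <- Inf
  best <- min(obj)
  cand_rows <- which(obj <= best + 1e-9)
  if (length(cand_rows) > 1L) {
    nact <- rowSums(S[cand_rows, , drop = FALSE] != 0L)
    cand_rows <- cand_rows[nact == min(nact)]
    if (length(cand_rows) > 1L) {
      keys <- vapply(cand_rows, function(i) {
        paste(sort(nodes[S[i, ] != 0L]), collapse = "|")
      }, character(1))
      cand_rows <- cand_rows[order(keys)][1]
    }
  }
  stats::setNames(S[cand_rows[1], ], nodes)
}

# Exact depth-first branch-and-bound over node states (the "ilp" backend:
# same optimum and tie-breaking as full enumeration, pruned by an
# admissible bound). Nodes are branched in topological order when the
# component is acyclic, which makes the incremental support check complete
# (all in-edge sources are decided first) so leaves need no constructive
# check; cyclic components fall back to a leaf check.
solve_component_bnb <- function(nodes, edges, meas, candidates, beta,
                                lambda, scores) {
  ord <- topo_order(nodes, edges)
  dag <- !is.null(ord)
  if (!dag) {
    # BFS layers from candidates, then name (deterministic)
    cand_here <- intersect(nodes, candidates)
    depth <- stats::setNames(rep(Inf, length(nodes)), nodes)
    depth[cand_here] <- 0
    frontier <- cand_here; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(edges$target[edges$source %in% frontier])
      nxt <- nxt[depth[nxt] > d]
      depth[nxt] <- d
      frontier <- nxt
    }
    ord <- nodes[order(depth, nodes)]
  }
  n <- length(ord)
  pos <- stats::setNames(seq_len(n), ord)
  is_cand <- ord %in% candidates
  w_meas <- numeric(n); s_meas <- integer(n)
  if (nrow(meas)) {
    mm <- meas[meas$tf %in% ord, , drop = FALSE]
    w_meas[pos[mm$tf]] <- mm$weight
    s_meas[pos[mm$tf]] <- mm$sign
  }
  rew <- numeric(n); rsgn <- integer(n)
  if (!is.null(scores)) {
    sn <- intersect(names(scores), ord)
    rew[pos[sn]] <- abs(scores[sn])
    rsgn[pos[sn]] <- as.integer(sign(scores[sn]))
  }
  rem_reward <- rev(cumsum(rev(lambda * rew)))
  in_src <- vector("list", n); in_sgn <- vector("list", n)
  for (i in seq_len(n)) {
    ine <- which(edges$target == ord[i])
    in_src[[i]] <- unname(pos[edges$source[ine]])
    in_sgn[[i]] <- edges$sign[ine]
  }

  env <- new.env(parent = emptyenv())
  env$best_obj <- Inf; env$best_nact <- Inf; env$best_key <- "~"
  env$best_state <- integer(n)
  state <- integer(n)

  recurse <- function(i, cost, nact) {
    if (i > n) {
      if (!dag) {
        st <- stats::setNames(state, ord)
        if (is.null(support_structure(st, edges, ord[is_cand]))) return(invisible())
      }
      key <- NULL
      accept <- cost < env$best_obj - 1e-9
      if (!accept && cost < env$best_obj + 1e-9) {
        if (nact < env$best_nact) {
          accept <- TRUE
        } else if (nact == env$best_nact) {
          key <- paste(sort(ord[state != 0L]), collapse = "|")
          accept <- key < env$best_key
        }
      }
      if (accept) {
        env$best_obj <- cost; env$best_nact <- nact
        env$best_state <- state
        env$best_key <- key %||% paste(sort(ord[state != 0L]), collapse = "|")
      }
      return(invisible())
    }
    slack <- rem_reward[i]
    for (sv in c(0L, 1L, -1L)) {
      # support check: an active non-candidate needs a decided usable
      # in-edge (complete for DAG/topological order) or an undecided source
      if (sv != 0L && !is_cand[i]) {
        src <- in_src[[i]]
        if (!length(src)) next
        usable <- (src > i) |
          (state[src] != 0L & state[src] * in_sgn[[i]] == sv)
        if (!any(usable)) next
      }
      dc <- 0
      if (w_meas[i] > 0 && sv != s_meas[i]) dc <- dc + w_meas[i]
      if (sv != 0L) {
        dc <- dc + beta
        if (rsgn[i] == sv) dc <- dc - lambda * rew[i]
      }
      new_cost <- cost + dc
      if (new_cost - slack <= env$best_obj + 1e-9) {
        state[i] <<- sv
        recurse(i + 1L, new_cost, nact + (sv != 0L))
        state[i] <<- 0L
      }
    }
    invisible()
  }
  recurse(1L, 0, 0L)
  stats::setNames(env$best_state, ord)[nodes]
}

#' Contextualize a PKN against measured TF activities
#'
#' Finds the exact optimum of the CARNIVAL-style objective (see the module
#' header) over node states {-1, 0, +1}. The network is first restricted
#' to the forward closure of the candidate nodes (nothing outside it can
#' ever be active) and decomposed into weakly connected components, which
#' are solved independently. Measured TFs outside the closure contribute
#' their mismatch weight as a constant. Among co-optimal solutions the one
#' with the fewest active nodes, then the lexicographically smallest active
#' node set, is returned.
#'
#' @param pkn data.frame(source, sign, target) (e.g. from
#'   [preprocess_pkn()])
#' @param measurements data.frame(tf, sign, weight) with weight > 0 (e.g.
#'   |NES|); TFs absent from the PKN are dropped with a log entry
#' @param candidates candidate perturbation nodes (must be PKN nodes)
#' @param beta node-parsimony weight (default 0.9)
#' @param node_scores optional named vector of signed node rewards (e.g.
#'   pathway scores propagated to nodes)
#' @param lambda reward weight (default 0.1)
#' @param solver `"ilp"` (exact branch-and-bound) or `"exhaustive"` (full
#'   enumeration oracle; refuses components with more than
#'   `max_exhaustive` non-measured nodes)
#' @param max_exhaustive size guard for the exhaustive backend
#' @return list: `state` (named -1/0/+1 vector over closure nodes),
#'   `active_edges`, `objective`, `mismatch_term`, `size_term`,
#'   `reward_term`
#' @export
carnival_solve <- function(pkn, measurements, candidates, beta = 0.9,
                           node_scores = NULL, lambda = 0.1,
                           solver = c("ilp", "exhaustive"),
                           max_exhaustive = 15L) {
  solver <- match.arg(solver)
  nodes_all <- unique(c(pkn$source, pkn$target))
  if (!all(candidates %in% nodes_all)) {
    stopf("candidates absent from the PKN: %s",
          paste(setdiff(candidates, nodes_all), collapse = ", "))
  }
  drop <- !(measurements$tf %in% nodes_all)
  if (any(drop)) {
    sc_log("carnival_solve: dropping %d measurement(s) absent from the PKN",
           sum(drop))
    measurements <- measurements[!drop, , drop = FALSE]
  }
  if (nrow(measurements) && any(measurements$weight <= 0)) {
    stopf("measurement weights must be positive")
  }
  # forward closure of the candidates
  closure <- candidates
  repeat {
    nxt <- unique(pkn$target[pkn$source %in% closure])
    add <- setdiff(nxt, closure)
    if (!length(add)) break
    closure <- c(closure, add)
  }
  closure <- sort(closure)
  edges <- pkn[pkn$source %in% closure & pkn$target %in% closure, , drop = FALSE]
  out_meas <- measurements[!(measurements$tf %in% closure), , drop = FALSE]
  const_mismatch <- sum(out_meas$weight)
  meas <- measurements[measurements$tf %in% closure, , drop = FALSE]

  # weakly connected components of the closure
  comp <- stats::setNames(seq_along(closure), closure)
  changed <- TRUE
  while (changed) {   # label propagation; labels only ever decrease
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      s <- edges$source[i]; t <- edges$target[i]
      m <- min(comp[[s]], comp[[t]])
      if (comp[[s]] != m) { comp[[s]] <- m; changed <- TRUE }
      if (comp[[t]] != m) { comp[[t]] <- m; changed <- TRUE }
    }
  }
  state <- stats::setNames(integer(length(closure)), closure)
  for (cid in unique(comp)) {
    cn <- names(comp)[comp == cid]
    ce <- edges[edges$source %in% cn, , drop = FALSE]
    cm <- meas[meas$tf %in% cn, , drop = FALSE]
    cs <- if (!is.null(node_scores)) node_scores[intersect(names(node_scores), cn)]
    st <- if (solver == "exhaustive") {
      solve_component_exhaustive(cn, ce, cm, candidates, beta, lambda, cs,
                                 max_exhaustive)
    } else {
      solve_component_bnb(cn, ce, cm, candidates, beta, lambda, cs)
    }
    state[cn] <- st[cn]
  }
  active_edges <- support_structure(state, edges, candidates)
  terms <- solution_objective(state, meas, beta, lambda, node_scores)
  list(state = state,
       active_edges = active_edges,
       objective = terms$objective + const_mismatch,
       mismatch_term = terms$mismatch + const_mismatch,
       size_term = terms$size,
       reward_term = terms$reward)
}

#' Consensus targets from reciprocal pairwise solutions
#'
#' A node is reciprocal-consistent for contrast X when it is active with
#' state s in REF_vs_X and either active with -s in X_vs_REF or absent
#' there (`single_direction = "consistent"`, the default; `"strict"`
#' requires the negated state). Nodes active with the same state in both
#' directions are contradictory and excluded. The consensus is the
#' three-way intersection of (node, mode) pairs over all REF-side
#' contrasts, minus the measured TFs.
#'
#' @param solutions named list of [carnival_solve()] results; names like
#'   `"MES_vs_IMR"` and `"IMR_vs_MES"` for every other subtype
#' @param exclude nodes excluded from the consensus (the measured TFs)
#' @param reference the reference subtype (default "MES")
#' @param single_direction treatment of nodes active in only one direction
#' @return data.frame(node, mode, supported_contrasts, reciprocal_consistent)
#' @export
pairwise_consensus <- function(solutions, exclude = character(0),
                               reference = "MES",
                               single_direction = c("consistent", "strict")) {
  single_direction <- match.arg(single_direction)
  fwd_names <- grep(paste0("^", reference, "_vs_"), names(solutions),
                    value = TRUE)
  if (!length(fwd_names)) stopf("no %s-side solutions found", reference)
  per_contrast <- list()
  for (fn in fwd_names) {
    x <- sub(paste0("^", reference, "_vs_"), "", fn)
    rn <- paste0(x, "_vs_", reference)
    if (!(rn %in% names(solutions))) stopf("missing reciprocal solution %s", rn)
    f <- solutions[[fn]]$state
    r <- solutions[[rn]]$state
    act <- names(f)[f != 0L]
    keep <- vapply(act, function(v) {
      rs <- if (v %in% names(r)) r[[v]] else 0L
      if (rs == f[[v]]) return(FALSE)              # contradictory
      if (rs == -f[[v]]) return(TRUE)
      single_direction == "consistent"             # absent in reverse
    }, logical(1))
    per_contrast[[x]] <- data.frame(node = act[keep],
                                    mode = unname(f[act[keep]]),
                                    stringsAsFactors = FALSE)
  }
  common <- Reduce(function(a, b) merge(a, b, by = c("node", "mode")),
                   per_contrast)
  common <- common[!(common$node %in% exclude), , drop = FALSE]
  common <- common[order(common$node), , drop = FALSE]
  if (!nrow(common)) {
    return(data.frame(node = character(0), mode = integer(0),
                      supported_contrasts = character(0),
                      reciprocal_consistent = logical(0)))
  }
  data.frame(node = common$node, mode = common$mode,
             supported_contrasts = paste(names(per_contrast), collapse = ","),
             reciprocal_consistent = TRUE, stringsAsFactors = FALSE)
}
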