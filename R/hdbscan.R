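#' @name hdbscan_cluster
#' @title Hierarchical density-based clustering (package implementation)
#'
#' @description
#' HDBSCAN over a low-dimensional embedding: core distances from the
#' `min_samples`-th nearest neighbour, mutual-reachability distances,
#' single-linkage hierarchy (via [stats::hclust]) on those distances,
#' condensation of the dendrogram at `min_cluster_size`, and
#' excess-of-mass cluster selection. Points belonging to no selected
#' cluster receive the reserved noise label `"noise"`; clusters are
#' labelled `"0"`, `"1"`, ... in decreasing size order.
#'
#' @param emb Numeric matrix of embedding coordinates (rows = points).
#' @param min_cluster_size Smallest subtree treated as a cluster; default
#'   scales with the number of points (`max(10, 15% of n)`), reflecting
#'   that a zebra finch repertoire rarely exceeds a handful of syllable
#'   types; override for richer repertoires.
#' @param min_samples Neighbour rank defining the core distance (the
#'   density-smoothing scale), kept moderate by default so that distinct
#'   nearby clusters are not bridged.
#' @return Character vector of labels, one per row of `emb`, with
#'   attribute `"n_clusters"`.
#' @export
hdbscan_cluster <- function(emb, min_cluster_size = NULL, min_samples = 10L) {
  emb <- as.matrix(emb)
  n <- nrow(emb)
  if (is.null(min_cluster_size)) min_cluster_size <- max(10L, round(0.15 * n))
  if (is.null(min_samples)) min_samples <- 10L
  min_cluster_size <- max(2L, as.integer(min_cluster_size))
  if (n < 2L * min_cluster_size) {
    out <- rep("0", n)
    attr(out, "n_clusters") <- 1L
    return(out)
  }
  D <- as.matrix(stats::dist(emb))
  k <- min(min_samples + 1L, n)         # +1: self distance is 0
  core <- apply(D, 1, function(r) sort(r, partial = k)[k])
  MR <- pmax(D, outer(core, core, pmax))
  hc <- stats::hclust(stats::as.dist(MR), method = "single")
  labs <- .condense_and_extract(hc, n, min_cluster_size)
  # relabel by decreasing size, noise last
  tab <- sort(table(labs[labs != "noise"]), decreasing = TRUE)
  map <- stats::setNames(as.character(seq_along(tab) - 1L), names(tab))
  out <- ifelse(labs == "noise", "noise", map[labs])
  attr(out, "n_clusters") <- length(tab)
  out
}

# Condense the single-linkage tree and run excess-of-mass selection.
# Internal nodes of hclust: rows of merge; heights increasing.
.condense_and_extract <- function(hc, n, mcs) {
  m <- hc$merge
  h <- hc$height
  n_int <- nrow(m)
  # members and size of each internal node (indices into merge rows)
  members <- vector("list", n_int)
  for (i in seq_len(n_int)) {
    get_side <- function(v) if (v < 0) -v else members[[v]]
    members[[i]] <- c(get_side(m[i, 1]), get_side(m[i, 2]))
  }
  sizes <- lengths(members)
  lam <- 1 / pmax(h, 1e-12)             # lambda = 1/distance

  # condensed clusters: id, birth lambda, parent condensed id
  cl_birth <- numeric(0); cl_parent <- integer(0)
  new_cluster <- function(birth, parent) {
    cl_birth[length(cl_birth) + 1L] <<- birth
    cl_parent[length(cl_parent) + 1L] <<- parent
    length(cl_birth)
  }
  root_id <- new_cluster(0, 0L)
  pt_lambda <- numeric(n)               # lambda at which each point leaves
  pt_cluster <- integer(n)              # the condensed cluster it leaves from
  cl_stab_extra <- numeric(1)           # split contribution per cluster

  # walk top-down; stack holds (raw node, condensed cluster id)
  stack <- list(c(n_int, root_id))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top[1]; cid <- top[2]
    lambda_here <- lam[node]
    kids <- m[node, ]
    ksz <- ifelse(kids < 0, 1L, sizes[pmax(kids, 1L)])
    big <- ksz >= mcs
    drop_points <- function(v) {
      pts <- if (v < 0) -v else members[[v]]
      pt_lambda[pts] <<- lambda_here
      pt_cluster[pts] <<- cid
    }
    if (all(big)) {
      # true split: parent dies here, two child clusters are born
      pts <- members[[node]]
      # parent stability: all its points persist to the split
      cl_stab_extra[cid] <- cl_stab_extra[cid] +
        length(pts) * (lambda_here - cl_birth[cid])
      for (s in 1:2) {
        ncid <- new_cluster(lambda_here, cid)
        cl_stab_extra[ncid] <- 0
        stack[[length(stack) + 1L]] <- c(kids[s], ncid)
      }
    } else if (any(big)) {
      small <- kids[!big]; large <- kids[big]
      for (v in small) drop_points(v)
      if (large < 0) {
        drop_points(large)               # single point remains: falls out too
      } else {
        stack[[length(stack) + 1L]] <- c(large, cid)
      }
    } else {
      for (v in kids) drop_points(v)
    }
  }

  n_cl <- length(cl_birth)
  # point fall-out contributions to the cluster they left
  stability <- cl_stab_extra
  if (length(stability) < n_cl) stability <- c(stability, rep(0, n_cl - length(stability)))
  fell <- which(pt_cluster > 0L)
  for (p in fell) {
    cid <- pt_cluster[p]
    stability[cid] <- stability[cid] + (pt_lambda[p] - cl_birth[cid])
  }

  children <- split(seq_len(n_cl), factor(cl_parent, levels = 0:n_cl))
  selected <- logical(n_cl)
  score <- numeric(n_cl)
  for (cid in rev(seq_len(n_cl))) {     # children have larger ids: bottom-up
    kids <- children[[as.character(cid)]]
    if (length(kids) == 0L) {
      selected[cid] <- cid != root_id
      score[cid] <- stability[cid]
    } else {
      sub <- sum(score[kids])
      if (cid != root_id && stability[cid] >= sub) {
        selected[cid] <- TRUE
        # deselect all descendants
        desc <- kids
        while (length(desc)) {
          selected[desc] <- FALSE
          desc <- unlist(children[as.character(desc)], use.names = FALSE)
        }
        score[cid] <- stability[cid]
      } else {
        score[cid] <- sub
      }
    }
  }
  if (!any(selected)) selected[root_id] <- TRUE

  # each point belongs to the nearest selected ancestor of its fall-out cluster
  labs <- rep("noise", n)
  sel_of <- integer(n_cl)               # memoized nearest selected ancestor
  nearest_selected <- function(cid) {
    cur <- cid
    while (cur != 0L) {
      if (selected[cur]) return(cur)
      cur <- cl_parent[cur]
    }
    0L
  }
  for (cid in seq_len(n_cl)) sel_of[cid] <- nearest_selected(cid)
  for (p in seq_len(n)) {
    cid <- pt_cluster[p]
    if (cid > 0L && sel_of[cid] > 0L) labs[p] <- as.character(sel_of[cid])
  }
  labs
}
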