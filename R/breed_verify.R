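#' Pairwise identity-by-state distance matrix
#'
#' For two diploid dosage vectors the IBS distance is
#' `1 - (IBS2 + 0.5 * IBS1) / sites compared`, where IBS2 counts sites with
#' identical genotypes and IBS1 sites sharing exactly one allele; this equals
#' the mean of `|g_i - g_j| / 2` over mutually non-missing sites. Not
#' guaranteed to be metric.
#'
#' @param gm a [genotype_matrix()].
#' @param site_index optional variant subset (integer or logical index).
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
ibs_distance <- function(gm, site_index = NULL) {
  d <- gm$dosages
  if (!is.null(site_index)) d <- d[, site_index, drop = FALSE]
  n <- nrow(d)
  if (n < 2) stop("need at least 2 samples")
  D <- matrix(0, n, n, dimnames = list(rownames(d), rownames(d)))
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    diff <- abs(d[rest, , drop = FALSE] -
                  matrix(d[i, ], length(rest), ncol(d), byrow = TRUE))
    cmp <- rowSums(!is.na(diff))
    if (any(cmp == 0)) {
      j <- rest[which(cmp == 0)[1]]
      stop("no comparable sites for pair (", rownames(d)[i], ", ",
           rownames(d)[j], ")")
    }
    D[i, rest] <- D[rest, i] <- rowSums(diff, na.rm = TRUE) / (2 * cmp)
  }
  D
}

#' Bootstrapped IBS distance matrices
#'
#' Each replicate resamples sites with replacement to the original site count
#' (the standard phylogenetic bootstrap over characters) and recomputes the
#' IBS distance matrix. Reproducible from `seed`.
#'
#' @param gm a [genotype_matrix()].
#' @param n_boot number of replicates, default 100.
#' @param seed integer seed.
#' @return list of distance matrices.
#' @export
bootstrap_distances <- function(gm, n_boot = 100, seed = 1) {
  stopifnot(n_boot >= 1)
  p <- n_variants(gm)
  with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      ibs_distance(gm, site_index = sample.int(p, p, replace = TRUE))
    })
  })
}

#' Neighbor-joining tree
#'
#' Classical agglomeration: repeatedly join the pair minimising the
#' rate-corrected Q-criterion, with branch lengths from the standard
#' formulas. Ties in Q are broken toward the lowest (row-major) index pair.
#' Negative branch lengths are clamped to zero; the number of clamped edges
#' is reported in the `"n_clamped"` attribute.
#'
#' @param D symmetric distance matrix with labels as dimnames (>= 3 taxa).
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix not symmetric")
  if (any(D < 0)) stop("negative distances")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  n_clamped <- 0L
  clamp <- function(x) {
    if (x < 0) { n_clamped <<- n_clamped + 1L; 0 } else x
  }
  frag <- labels  # newick fragment per active node
  act <- seq_len(n)
  Dm <- D
  while (length(act) > 3) {
    r <- length(act)
    Da <- Dm[act, act]
    R <- rowSums(Da)
    Q <- (r - 2) * Da - outer(R, R, `+`)
    diag(Q) <- Inf
    # lowest row-major index pair among minima
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    a <- idx[1, 1]; b <- idx[1, 2]
    dab <- Da[a, b]
    la <- clamp(dab / 2 + (R[a] - R[b]) / (2 * (r - 2)))
    lb <- clamp(dab - (dab / 2 + (R[a] - R[b]) / (2 * (r - 2))))
    ia <- act[a]; ib <- act[b]
    newfrag <- sprintf("(%s:%.15g,%s:%.15g)", frag[ia], la, frag[ib], lb)
    # distances from the new node to the remaining actives
    others <- act[-c(a, b)]
    dnew <- (Dm[ia, others] + Dm[ib, others] - dab) / 2
    Dm[ia, others] <- Dm[others, ia] <- dnew
    frag[ia] <- newfrag
    act <- c(act[-c(a, b)], ia)
    act <- sort(act)
  }
  i <- act[1]; j <- act[2]; k <- act[3]
  li <- clamp((Dm[i, j] + Dm[i, k] - Dm[j, k]) / 2)
  lj <- clamp((Dm[i, j] + Dm[j, k] - Dm[i, k]) / 2)
  lk <- clamp((Dm[i, k] + Dm[j, k] - Dm[i, j]) / 2)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[i], li, frag[j], lj, frag[k], lk)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "n_clamped") <- n_clamped
  tree
}

# canonical split representation: logical vector over sorted labels, side not
# containing the first label; NULL for trivial splits
tree_splits <- function(tree, universe) {
  n <- length(universe)
  tip_idx <- match(tree$tip.label, universe)
  if (anyNA(tip_idx)) stop("tree has leaves outside the common leaf set")
  nt <- length(tree$tip.label)
  # tips under each internal node by postorder accumulation
  below <- vector("list", nt + tree$Nnode)
  for (t in seq_len(nt)) below[[t]] <- tip_idx[t]
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(eo))) {
    p <- eo[e, 1]; ch <- eo[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  out <- list()
  seen <- character(0)
  for (node in (nt + 1):(nt + tree$Nnode)) {
    side <- rep(FALSE, n)
    side[below[[node]]] <- TRUE
    sz <- sum(side)
    if (sz < 2 || sz > n - 2) next
    if (side[1]) side <- !side
    key <- paste(which(side), collapse = ",")
    if (key %in% seen) next  # both root children describe the same split
    seen <- c(seen, key)
    out[[length(out) + 1]] <- side
  }
  out
}

#' Strict majority-rule consensus tree
#'
#' Retains exactly the bipartitions present in more than half of the input
#' trees (no greedy completion with compatible minority splits) and annotates
#' each retained internal edge with its support fraction as a node label.
#'
#' @param trees list of `ape::phylo` trees over an identical leaf set.
#' @return an `ape::phylo` consensus tree with `node.label` support fractions.
#' @export
majority_consensus <- function(trees) {
  if (length(trees) < 1) stop("need at least one tree")
  universe <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), universe))
      stop("trees have differing leaf sets")
  }
  tally <- new.env(hash = TRUE)
  for (tr in trees) {
    for (s in tree_splits(tr, universe)) {
      key <- paste(which(s), collapse = ",")
      cur <- if (is.null(tally[[key]])) 0L else tally[[key]]
      tally[[key]] <- cur + 1L
    }
  }
  keys <- ls(tally)
  freq <- vapply(keys, function(k) tally[[k]], integer(1)) / length(trees)
  keep <- keys[freq > 0.5]
  supports <- freq[freq > 0.5]
  clusters <- lapply(keep, function(k) as.integer(strsplit(k, ",")[[1]]))
  build_consensus_tree(universe, clusters, supports)
}

# assemble a (possibly multifurcating) rooted-representation tree from
# pairwise-compatible clusters over `universe`; supports become node labels
build_consensus_tree <- function(universe, clusters, supports) {
  n <- length(universe)
  ord <- order(vapply(clusters, length, integer(1)), decreasing = TRUE)
  clusters <- clusters[ord]
  supports <- supports[ord]
  nc <- length(clusters)
  # parent cluster of each cluster: smallest strict superset (already sorted
  # by decreasing size, so scan earlier clusters backwards)
  parent <- rep(0L, nc)  # 0 = root
  for (i in seq_len(nc)) {
    if (i == 1) next
    for (j in (i - 1):1) {
      if (all(clusters[[i]] %in% clusters[[j]])) { parent[i] <- j; break }
    }
  }
  # tip parents: deepest (smallest) cluster containing the tip
  tip_parent <- rep(0L, n)
  for (i in seq_len(nc)) tip_parent[clusters[[i]]] <- i
  children_cl <- split(seq_len(nc), factor(parent, levels = 0:nc))
  children_tip <- split(seq_len(n), factor(tip_parent, levels = 0:nc))
  nwk_of <- function(ci) {
    parts <- character(0)
    for (t in children_tip[[as.character(ci)]])
      parts <- c(parts, universe[t])
    for (cc in children_cl[[as.character(ci)]])
      parts <- c(parts, paste0(nwk_of(cc), sprintf("%.10g", supports[cc])))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(nwk_of(0L), ";")
  tree <- ape::read.tree(text = txt)
  tree
}

#' Flag samples that do not cluster with their breed
#'
#' For each breed with at least two samples, the breed's *home clade* is the
#' consensus split side that maximises (breed members present) minus
#' (non-members present), restricted to sides containing more than half of
#' the breed's samples; ties go first to the side holding more breed
#' members, then to the smaller side. Samples of the breed absent from its
#' home clade are flagged. Singleton breeds are skipped (one sample cannot
#' cluster).
#'
#' @param tree consensus tree (`ape::phylo`) whose tips are sample ids.
#' @param meta data.frame with `sample_id` and `breed`.
#' @return data.frame with one row per flagged sample: `sample_id`, `breed`,
#'   `clade_size`, `breed_in_clade`, `breed_total`, `reason`.
#' @export
flag_breed_outliers <- function(tree, meta) {
  tips <- tree$tip.label
  breed <- meta$breed[match(tips, meta$sample_id)]
  if (anyNA(breed)) stop("every leaf needs a breed label")
  universe <- sort(tips)
  splits <- tree_splits(tree, universe)
  # both sides of every split are candidate clades
  sides <- c(splits, lapply(splits, `!`))
  breed_u <- breed[match(universe, tips)]

  out <- list()
  for (b in unique(breed_u)) {
    members <- which(breed_u == b)
    k <- length(members)
    if (k < 2) next
    best <- NULL; best_key <- c(-Inf, -Inf, -Inf)
    for (s in sides) {
      inb <- sum(s[members])
      if (inb <= k / 2) next
      size <- sum(s)
      key <- c(inb - (size - inb), inb, -size)
      better <- FALSE
      for (q in 1:3) {
        if (key[q] > best_key[q]) { better <- TRUE; break }
        if (key[q] < best_key[q]) break
      }
      if (better) { best <- s; best_key <- key }
    }
    if (is.null(best)) next  # tree too unresolved to place the breed
    absent <- members[!best[members]]
    for (a in absent) {
      out[[length(out) + 1]] <- data.frame(
        sample_id = universe[a], breed = b,
        clade_size = sum(best), breed_in_clade = sum(best[members]),
        breed_total = k,
        reason = sprintf("outside home clade (%d/%d breed members in a clade of %d)",
                         sum(best[members]), k, sum(best)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), breed = character(0),
                      clade_size = integer(0), breed_in_clade = integer(0),
                      breed_total = integer(0), reason = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Breed-assignment verification pipeline
#'
#' Bootstrapped IBS distances, one neighbor-joining tree per replicate, a
#' strict majority-rule consensus, and outlier flagging against breed labels.
#'
#' @param gm a [genotype_matrix()] with breed labels in its sample table.
#' @param n_boot bootstrap replicates, default 100.
#' @param seed integer seed for the site resampling.
#' @return list with `consensus` (phylo), `trees`, `flags` (data.frame) and
#'   `distances` (the point-estimate IBS matrix).
#' @export
verify_breeds <- function(gm, n_boot = 100, seed = 1) {
  boots <- bootstrap_distances(gm, n_boot = n_boot, seed = seed)
  trees <- lapply(boots, neighbor_joining)
  cons <- majority_consensus(trees)
  flags <- flag_breed_outliers(cons, gm$samples)
  list(consensus = cons, trees = trees, flags = flags,
       distances = ibs_distance(gm))
}
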