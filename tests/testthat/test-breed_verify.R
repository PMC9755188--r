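test_that("IBS distance matches its definition on simple pairs", {
  # identical samples
  gm <- make_gm(rbind(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(unname(ibs_distance(gm)), matrix(0, 2, 2))
  # opposite homozygotes at every site
  gm2 <- make_gm(rbind(c(0, 0), c(2, 2)))
  expect_equal(ibs_distance(gm2)["s1", "s2"], 1)
  # one shared allele at the single site
  gm3 <- make_gm(cbind(c(1, 2)))
  expect_equal(ibs_distance(gm3)["s1", "s2"], 0.5)
  # symmetry and zero diagonal on a random fixture; pairs use only mutually
  # observed sites
  gm4 <- random_gm(6, 40, seed = 5, miss = 0.2)
  D <- ibs_distance(gm4)
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 6), paste0("s", 1:6)))
  expect_true(all(D >= 0 & D <= 1))
})

test_that("a pair with no comparable sites is reported by name", {
  d <- rbind(c(0, NA), c(NA, 2), c(1, 1))
  gm <- make_gm(d)
  expect_error(ibs_distance(gm), "s1.*s2")
})

test_that("bootstrap replicates are seed-reproducible and well-behaved", {
  gm <- random_gm(5, 60, seed = 8)
  b1 <- bootstrap_distances(gm, n_boot = 4, seed = 99)
  b2 <- bootstrap_distances(gm, n_boot = 4, seed = 99)
  expect_identical(b1, b2)
  expect_length(b1, 4)
  # degenerate panel where every site is identical: resampling cannot change
  # the distances, so each replicate equals the point estimate
  gmc <- make_gm(matrix(rep(c(0, 1, 2, 1, 0), 10), 5, 10))
  bc <- bootstrap_distances(gmc, n_boot = 3, seed = 1)
  for (B in bc) expect_equal(B, ibs_distance(gmc))
  # replicate mean stays within 3 bootstrap SEs of the point estimate
  boots <- bootstrap_distances(gm, n_boot = 200, seed = 3)
  ij <- cbind(1, 2)
  vals <- vapply(boots, function(B) B[ij], numeric(1))
  se <- sd(vals)
  expect_lt(abs(mean(vals) - ibs_distance(gm)[ij]), 3 * se + 1e-12)
})

test_that("neighbor joining solves the three-point configuration", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
})

test_that("neighbor joining recovers additive trees exactly", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    rt <- ape::rtree(7)
    D <- ape::cophenetic.phylo(rt)
    tr <- neighbor_joining(D)
    D2 <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_lt(max(abs(D2 - D)), 1e-9)
    # independent cross-check: same unrooted topology as ape's NJ
    expect_equal(ape::dist.topo(ape::unroot(tr),
                                ape::unroot(ape::nj(D)))[1], 0)
  }
})

test_that("neighbor joining validates input and breaks ties deterministically", {
  D <- matrix(runif(9), 3, 3)
  expect_error(neighbor_joining(D), "symmetric")
  Dn <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3, 3)
  expect_error(neighbor_joining(Dn), "negative")
  # fully tied distances: the lowest-index pair (1, 2) joins first, giving
  # the same tree on every run
  De <- matrix(1, 4, 4) - diag(4)
  dimnames(De) <- list(letters[1:4], letters[1:4])
  t1 <- neighbor_joining(De)
  t2 <- neighbor_joining(De)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # the (a, b) cherry is the one created by the tie-break
  parts <- ape::prop.part(ape::unroot(t1))
  expect_true(any(vapply(parts, function(p)
    setequal(t1$tip.label[p], c("a", "b")) ||
      setequal(t1$tip.label[p], c("c", "d")), logical(1))))
})

test_that("majority consensus keeps exactly the splits above half support", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  trees <- rep(list(t1), 100)
  cons <- majority_consensus(trees)
  expect_equal(ape::dist.topo(ape::unroot(cons), ape::unroot(t1))[1], 0)
  expect_true(all(as.numeric(cons$node.label[nzchar(cons$node.label)]) == 1))

  t2 <- ape::read.tree(text = "((A,B),(C,E),D);")
  t3 <- ape::read.tree(text = "((A,C),(B,D),E);")
  cons3 <- majority_consensus(list(t1, t2, t3))
  # {A,B} appears in 2/3 trees; {C,D} and {C,E} each once and must be gone
  labs <- as.numeric(cons3$node.label[nzchar(cons3$node.label)])
  expect_equal(labs, 2 / 3)
  parts <- ape::prop.part(cons3)
  labs3 <- attr(parts, "labels")
  sets <- lapply(parts, function(p) sort(labs3[p]))
  # the bipartition may be stored as {A,B} or its complement
  expect_true(any(vapply(sets, function(s)
    identical(s, c("A", "B")) ||
      identical(s, sort(setdiff(labs3, c("A", "B")))), logical(1))))
})

test_that("consensus supports equal brute-force bipartition tallies and
           ignore input order", {
  set.seed(11)
  pool <- lapply(1:3, function(i) ape::rtree(6, br = NULL))
  trees <- pool[c(1, 1, 1, 1, 2, 2, 2, 3, 3)]  # shared splits exceed 1/2
  universe <- sort(trees[[1]]$tip.label)
  # independent tally: canonicalised split frequency counted per input tree
  canon <- function(tipset) {
    side <- universe %in% tipset
    if (side[1]) side <- !side
    paste(which(side), collapse = ",")
  }
  tally <- table(unlist(lapply(trees, function(tr) {
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    keys <- vapply(pp, function(p) canon(labs[p]), character(1))
    unique(keys[vapply(pp, function(p) {
      k <- length(p); k >= 2 && k <= length(labs) - 2
    }, logical(1))])
  })))
  cons <- majority_consensus(trees)
  cp <- ape::prop.part(cons)
  clabs <- attr(cp, "labels")
  checked <- 0
  for (i in seq_along(cp)) {
    lab <- cons$node.label[i]
    if (is.na(lab) || !nzchar(lab)) next
    f_expected <- as.integer(tally[canon(clabs[cp[[i]]])]) / length(trees)
    expect_equal(as.numeric(lab), f_expected, tolerance = 1e-4)
    expect_gt(f_expected, 0.5)
    checked <- checked + 1
  }
  expect_gt(checked, 0)
  shuffled <- majority_consensus(rev(trees))
  expect_equal(ape::dist.topo(ape::unroot(cons), ape::unroot(shuffled))[1], 0)
  expect_error(majority_consensus(list(ape::rtree(4), ape::rtree(5))),
               "leaf sets")
})

test_that("breed outliers are flagged when placed in a foreign clade", {
  # a1 sits inside an otherwise-pure breed-B clade
  tr <- ape::read.tree(text = "(((b1,b2),(b3,a1)),((a2,a3),a4),(c1,c2));")
  meta <- data.frame(
    sample_id = c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "c1", "c2"),
    breed = c("A", "A", "A", "A", "B", "B", "B", "C", "C"))
  fl <- flag_breed_outliers(tr, meta)
  expect_true("a1" %in% fl$sample_id)
  expect_false(any(c("b1", "b2", "b3", "c1", "c2") %in% fl$sample_id))
  # all breeds monophyletic: nothing flagged
  tr2 <- ape::read.tree(text = "((a1,(a2,a3)),((b1,b2),b3),(c1,c2));")
  expect_equal(nrow(flag_breed_outliers(tr2, meta)), 0L)
  # singleton breeds are skipped, not flagged
  meta3 <- meta; meta3$breed[meta3$sample_id == "c2"] <- "D"
  tr3 <- ape::read.tree(text = "((a1,(a2,a3)),((b1,b2),b3),(c1,c2));")
  fl3 <- flag_breed_outliers(tr3, meta3)
  expect_false(any(c("c1", "c2") %in% fl3$sample_id))
})

test_that("the verification pipeline flags injected mislabels end to end", {
  cfg <- sim_config(n_breeds = 6, n_samples = 36, size_range = c(6, 6),
                    n_snps = 400, fst = 0.2, missingness = 0.01)
  st <- generate_study(cfg, seed = 11)
  inj <- inject_mislabels(st$gm, 3, seed = 4)
  vb <- verify_breeds(inj$gm, n_boot = 30, seed = 9)
  expect_setequal(vb$flags$sample_id, inj$injected$sample_id)
})
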