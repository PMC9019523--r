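test_that("clade extraction keeps the stem and flags non-monophyly", {
  tr <- worked_tree()
  cl <- extract_clade(tr, c("A", "B"))
  expect_setequal(cl$tip.label, c("A", "B"))
  expect_equal(cl$root.edge, 2)
  expect_equal(sort(cl$edge.length), c(1, 1))
  ## whole tree: stem 0
  full <- extract_clade(tr, c("A", "B", "C"))
  expect_equal(full$root.edge, 0)
  expect_equal(total_pd(full), 7)
  ## single tip: stem is the pendant edge
  one <- extract_clade(tr, "C")
  expect_equal(one$root.edge + sum(one$edge.length), 3)
  ## intruder named in the error
  tr2 <- ape::read.tree(text = "((A:1,C:1):2,B:3);")
  expect_error(extract_clade(tr2, c("A", "B")), "C")
  ## original tree untouched
  expect_equal(ape::write.tree(tr), "((A:1,B:1):2,C:3);")
})

test_that("rescaling preserves edge ratios and hits the target depth", {
  tr <- worked_tree()
  cl <- extract_clade(tr, c("A", "B"))     # depth 3
  r <- rescale_clade(cl, 6)
  expect_equal(r$root.edge, 4)
  expect_equal(sort(r$edge.length), c(2, 2))
  expect_equal(r$root.edge + max(ape::node.depth.edgelength(r)), 6)
  ## identity when target equals current depth
  same <- rescale_clade(cl, 3)
  expect_equal(same$edge.length, cl$edge.length)
  ## halving
  half <- rescale_clade(cl, 1.5)
  expect_equal(half$edge.length, cl$edge.length / 2)
  ## ratio preservation on a random clade
  set.seed(31)
  phy <- random_bd_tree(12)
  node <- phy$edge[1, 2]                       # first non-root internal node
  if (node <= ape::Ntip(phy)) node <- phy$edge[2, 1]
  taxa <- phy$tip.label[unlist(phangorn::Descendants(phy, node, "tips"))]
  cl2 <- extract_clade(phy, taxa)
  r2 <- rescale_clade(cl2, 42)
  expect_equal(r2$edge.length / r2$edge.length[1],
               cl2$edge.length / cl2$edge.length[1], tolerance = 1e-12)
})

test_that("grafting a rescaled clade preserves ultrametricity and depths", {
  set.seed(32)
  bb <- ape::rphylo(6, 0.3, 0.1)
  bb$tip.label <- paste0("G", 1:6)
  donor <- ape::rphylo(8, 0.4, 0.1)
  donor$tip.label <- paste0("s", 1:8)
  target <- bb$edge.length[bb$edge[, 2] == which(bb$tip.label == "G3")]
  clade <- extract_clade(donor, paste0("s", 1:8))
  clade <- rescale_clade(clade, target)
  merged <- graft_clade(bb, "G3", clade)
  expect_equal(ape::Ntip(merged), 13)
  expect_lt(ultrametric_spread(merged), 1e-9)
  expect_false("G3" %in% merged$tip.label)
  ## graft then extract round-trips the clade
  back <- extract_clade(merged, paste0("s", 1:8))
  expect_equal(back$root.edge + max(ape::node.depth.edgelength(back)),
               target, tolerance = 1e-9)
  expect_equal(phangorn::RF.dist(back, clade), 0)
})

test_that("grafting a one-tip clade renames the placeholder", {
  tr <- worked_tree()
  one <- ape::read.tree(text = "(Z:1);")
  one$root.edge <- 2
  out <- graft_clade(tr, "C", one)
  expect_true("Z" %in% out$tip.label)
  expect_equal(total_pd(out), 7)  # pendant 3 replaced by 2 + 1
  expect_error(graft_clade(tr, "NOPE", one), "not found")
})

test_that("missing groups are inserted at the reference stem ratio", {
  backbone <- ape::read.tree(text = "(S:4,O:4);")
  refb <- ape::read.tree(text = "((G:1,S:2):1,O:2);")
  out <- place_missing_groups(backbone, refb, refb, "G")
  expect_true("G" %in% out$tip.label)
  stem <- function(phy, lab)
    phy$edge.length[phy$edge[, 2] == which(phy$tip.label == lab)]
  expect_equal(stem(out, "G"), 2)          # 0.5 x sister stem 4
  expect_equal(stem(out, "S"), 2)          # sister stem split at age 2
  expect_lt(ultrametric_spread(out), 1e-9)
  ## empty missing set: identity
  expect_identical(place_missing_groups(backbone, refb, refb, character()),
                   backbone)
})

test_that("misplaced species reattach at the family crown as a polytomy", {
  ## family F = {A,B,C} with crown age 8; X belongs to F but sits outside
  tr <- ape::read.tree(
    text = "(((A:5,B:5):3,C:8):4,(X:10,D:10):2);")
  tax <- data.frame(species = c("A", "B", "C", "X", "D"),
                    order = "O1",
                    family = c("F", "F", "F", "F", "G"),
                    stringsAsFactors = FALSE)
  mis <- data.frame(species = "X", true_family = "F",
                    stringsAsFactors = FALSE)
  expect_false(families_monophyletic(tr, tax))
  out <- repair_nonmonophyly(tr, tax, mis)
  expect_true(families_monophyletic(out, tax))
  i <- which(out$tip.label == "X")
  expect_equal(out$edge.length[out$edge[, 2] == i], 8)  # crown age
  expect_lt(ultrametric_spread(out), 1e-9)              # tip at the present
  crown <- ape::getMRCA(out, c("A", "B", "C"))
  expect_equal(out$edge[out$edge[, 2] == i, 1], crown)  # basal polytomy
  ## empty misplaced list: identity
  expect_identical(repair_nonmonophyly(tr, tax, mis[0, ]), tr)
  expect_error(repair_nonmonophyly(tr, tax,
    data.frame(species = "X", true_family = "NOPE")), "absent")
})

test_that("taxonomy reconciliation prunes and reports", {
  tr <- worked_tree()
  tax <- data.frame(species = c("A", "C", "Z"), order = "O1", family = "F1")
  out <- reconcile_taxonomy(tr, tax)
  expect_equal(ape::write.tree(out$tree), "(A:3,C:3);")
  expect_equal(out$report$dropped, "B")
  expect_equal(out$report$missing, "Z")
  ## identity when everything is recognized
  tax2 <- data.frame(species = c("A", "B", "C"), order = "O1", family = "F1")
  out2 <- reconcile_taxonomy(tr, tax2)
  expect_equal(ape::write.tree(out2$tree), "((A:1,B:1):2,C:3);")
  expect_length(out2$report$dropped, 0)
  expect_error(reconcile_taxonomy(tr, data.frame(species = "Q")), "dropped")
})

test_that("pruning preserves pairwise path lengths among retained tips", {
  set.seed(33)
  phy <- random_bd_tree(20)
  keep <- phy$tip.label[1:12]
  tax <- data.frame(species = keep, order = "O1", family = "F1")
  pruned <- reconcile_taxonomy(phy, tax)$tree
  expect_equal(ape::cophenetic.phylo(pruned)[keep, keep],
               ape::cophenetic.phylo(phy)[keep, keep], tolerance = 1e-12)
})

test_that("run_merge recovers the truth tree from the fixture set", {
  cfg <- sim_config(n_species = 60, n_orders = 5, seed = 11)
  fx <- simulate_source_trees(cfg, n_donor_samples = 2)
  trees <- list(backbone = fx$backbone,
                reference_orders = fx$reference_orders,
                species = fx$donors)
  merged <- run_merge(fx$plan, trees, fx$taxonomy, fx$misplaced)
  expect_length(merged, 2)
  for (m in merged) {
    expect_equal(sort(m$tip.label), sort(fx$taxonomy$species))
    expect_lt(ultrametric_spread(m), 1e-6)
    expect_true(families_monophyletic(m, fx$taxonomy))
    shared <- setdiff(fx$truth$tip.label, fx$misplaced$species)
    expect_equal(phangorn::RF.dist(ape::keep.tip(m, shared),
                                   ape::keep.tip(fx$truth, shared)), 0)
    ## the omitted order is restored as a monophyletic clade
    osp <- fx$taxonomy$species[fx$taxonomy$order == fx$omitted_order]
    below <- m$tip.label[unlist(phangorn::Descendants(
      m, ape::getMRCA(m, osp), "tips"))]
    expect_setequal(setdiff(below, fx$misplaced$species),
                    setdiff(osp, fx$misplaced$species))
  }
})

test_that("run_merge handles single samples and empty plans", {
  cfg <- sim_config(n_species = 40, n_orders = 4, seed = 12)
  fx <- simulate_source_trees(cfg, n_donor_samples = 1)
  trees <- list(backbone = fx$backbone,
                reference_orders = fx$reference_orders,
                species = fx$donors)
  merged <- run_merge(fx$plan, trees, fx$taxonomy, fx$misplaced)
  expect_length(merged, 1)
  ## a plan with no grafts returns the reconciled backbone
  tax_bb <- data.frame(species = fx$backbone$tip.label,
                       order = fx$backbone$tip.label,
                       family = fx$backbone$tip.label)
  plain <- run_merge(merge_plan(backbone = "backbone"), trees, tax_bb)
  expect_length(plain, 1)
  expect_equal(sort(plain[[1]]$tip.label), sort(fx$backbone$tip.label))
  ## failures name the graft step
  bad_plan <- merge_plan("backbone",
    grafts = list(list(donor = "species", group = "NOPE", level = "order")))
  expect_error(run_merge(bad_plan, trees, fx$taxonomy), "NOPE")
})
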