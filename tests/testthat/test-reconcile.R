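test_that("congruent one-gene-per-species trees have no duplications", {
  st <- species_tree(ape::read.tree(text = "((A:1,B:1):1,C:1);"))
  gt <- gene_tree(ape::read.tree(text = "((A_1:1,B_1:1):1,C_1:1);"))
  rt <- lca_reconcile(gt, st)
  expect_false(any(rt$nodes$event == "duplication"))
  expect_equal(nrow(extract_duplications(rt)$duplications), 0L)
  part <- partition_branches(rt)
  expect_true(all(part == "single_copy_no_dup_family"))
  expect_equal(length(part), rt$index$n_node - 1L) # every non-root branch once
})

test_that("((a1,b1),(a2,b2)) on (A,B) puts a duplication at the root only", {
  gt <- gene_tree(ape::read.tree(text = "((A_1:1,B_1:1)x:1,(A_2:1,B_2:1)y:1)r;"))
  rt <- lca_reconcile(gt, two_species_tree())
  ev <- setNames(rt$nodes$event, rt$nodes$branch_id)
  expect_equal(unname(ev[c("r", "x", "y")]),
               c("duplication", "speciation", "speciation"))
})

test_that("same-species sister genes get a duplication parent", {
  gt <- gene_tree(ape::read.tree(text = "((A_1:1,A_2:1)p:1,B_1:1)r;"))
  rt <- lca_reconcile(gt, two_species_tree())
  ev <- setNames(rt$nodes$event, rt$nodes$branch_id)
  expect_equal(unname(ev["p"]), "duplication")
  expect_equal(unname(ev["r"]), "speciation")
})

test_that("unknown species names are reported", {
  gt <- gene_tree(ape::read.tree(text = "(A_1:1,Z_1:1);"))
  expect_error(lca_reconcile(gt, two_species_tree()), "Z")
})

test_that("NOTUNG-style D-suffixed labels can bypass LCA mapping", {
  gt <- gene_tree(ape::read.tree(text = "((A_1:1,B_1:1)nD:1,C_1:1)r;"))
  st <- species_tree(ape::read.tree(text = "((A:1,B:1):1,C:1);"))
  rt <- lca_reconcile(gt, st, use_labels = TRUE)
  ev <- setNames(rt$nodes$event, rt$nodes$branch_id)
  expect_equal(unname(ev["nD"]), "duplication")
  expect_equal(unname(ev["r"]), "speciation")
})

test_that("a root duplication on a 4-leaf tree yields 3-branch clades", {
  gt <- gene_tree(ape::read.tree(
    text = "((A_1:0.1,B_1:0.1)x:0.1,(A_2:0.1,B_2:0.1)y:0.1)r;"))
  rt <- lca_reconcile(gt, two_species_tree())
  dd <- extract_duplications(rt)
  expect_equal(nrow(dd$duplications), 1L)
  expect_equal(dd$duplications$clade1_n_branches, 3L)
  expect_equal(dd$duplications$clade2_n_branches, 3L)
  expect_equal(dd$duplications$clade1_ks, 0.3)
  expect_equal(dd$duplications$clade2_ks, 0.3)
  expect_equal(dd$duplications$depth_ks, 0) # root has no incoming branch
  ## clade1 holds the lexicographically smallest leaf
  cl1 <- dd$clade_branches$branch_id[dd$clade_branches$clade == 1]
  expect_true("A_1" %in% cl1)
  ## partition: everything below the root duplication is duplicated
  expect_true(all(partition_branches(rt) == "duplicated"))
})

test_that("nested duplications nest their clade branch sets", {
  gt <- gene_tree(ape::read.tree(
    text = "(((A_1:1,A_2:1)d2:1,A_3:1)d1:1,B_1:1)r;"))
  rt <- lca_reconcile(gt, two_species_tree())
  dd <- extract_duplications(rt)
  expect_setequal(dd$duplications$dup_id, c("d1", "d2"))
  cb <- dd$clade_branches
  inner <- cb$branch_id[cb$dup_id == "d2"]
  outer1 <- cb$branch_id[cb$dup_id == "d1" & cb$clade == 1]
  outer2 <- cb$branch_id[cb$dup_id == "d1" & cb$clade == 2]
  expect_true(all(inner %in% outer1) || all(inner %in% outer2))
})

test_that("a midway duplication splits contexts at its own branch", {
  ## duplication d above a 2-gene A clade, within a larger single-copy tree
  gt <- gene_tree(ape::read.tree(
    text = "((((A_1:1,A_2:1)d:1,B_1:1)s1:1,C_1:1)s2:1,D_1:1)r;"))
  st <- species_tree(ape::read.tree(text = "(((A:1,B:1):1,C:1):1,D:1);"))
  rt <- lca_reconcile(gt, st)
  part <- partition_branches(rt)
  expect_equal(unname(part[c("A_1", "A_2")]), rep("duplicated", 2))
  ## the duplication's own incoming branch is NOT more terminal than itself
  expect_equal(unname(part["d"]), "single_copy_in_dup_family")
  expect_equal(unname(part[c("B_1", "C_1", "D_1", "s1", "s2")]),
               rep("single_copy_in_dup_family", 5))
})

test_that("inferred duplications equal simulated truth, with Dollo-consistent counts", {
  for (seed in c(11, 12, 13)) {
    sim <- sim_family_fixture(seed, dup_rate = 0.3)
    rt <- sim$rtree
    inferred <- rt$nodes$branch_id[rt$nodes$event == "duplication"]
    expect_setequal(inferred, sim$truth$duplications)
    ## no-loss bookkeeping: total extra gene copies per species equal the
    ## species spanned by each duplication's mapping
    genes_per_sp <- table(sim$tree$species)
    si <- sim$species_tree$index
    span <- vapply(inferred, function(d) {
      v <- match(d, rt$index$branch_id)
      m <- rt$nodes$species[v]
      sv <- match(m, si$branch_id)
      length(si$branch_id[intersect(aaflux:::.subtree_nodes(si, sv),
                                    seq_len(si$n_tip))])
    }, 0L)
    expect_equal(sum(genes_per_sp - 1L), sum(span))
  }
})
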