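test_that("indel-region mask excludes runs of >1 gap but not single gaps", {
  aln <- family_alignment(c(s1 = "AC--GT", s2 = "ACWWGT"))
  expect_equal(which(mask_indel_regions(aln)), c(3L, 4L))
  aln2 <- family_alignment(c(s1 = "A-CGT", s2 = "AACGT"))
  expect_equal(sum(mask_indel_regions(aln2)), 0L)
  aln3 <- family_alignment(c(s1 = "-----", s2 = "AACGT"))
  expect_equal(which(mask_indel_regions(aln3)), 1:5)
})

test_that("fitch_score matches the worked small cases", {
  phy <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(fitch_score(c(a = "A", b = "A", c = "A", d = "A"), phy), 0L)
  expect_equal(fitch_score(c(a = "A", b = "A", c = "C", d = "C"), phy), 1L)
  expect_equal(fitch_score(c(a = "A", b = "C", c = "A", d = "C"), phy), 2L)
})

test_that("fitch_score equals brute-force enumeration on random instances", {
  set.seed(42)
  for (i in 1:60) {
    inst <- random_instance(n_tip = sample(3:7, 1), n_states = sample(2:5, 1))
    expect_equal(fitch_score(inst$column, inst$phy),
                 bf_fitch(inst$phy, inst$column, inst$alphabet),
                 info = paste("instance", i))
  }
})

test_that("fitch_score agrees with phangorn on amino-acid data", {
  set.seed(99)
  for (i in 1:20) {
    inst <- random_instance(n_tip = 6, n_states = 4, p_missing = 0)
    pd <- phangorn::phyDat(as.matrix(inst$column), type = "AA")
    expect_equal(fitch_score(inst$column, inst$phy),
                 as.integer(phangorn::parsimony(inst$phy, pd)))
  }
})

test_that("MPR enumeration covers the worked cases exactly", {
  phy <- five_leaf_tree()
  mp <- enumerate_mprs(five_leaf_column(), phy)
  expect_equal(mp$score, 1L)
  expect_length(mp$labelings, 1L)
  ev <- mpr_events(mp$labelings[[1]], phy)
  expect_equal(ev$branch_id, "n3")
  expect_equal(paste0(ev$source_aa, ev$dest_aa), "AC")

  phy2 <- ape::read.tree(text = "(g1:1,g2:1)r;")
  mp2 <- enumerate_mprs(c(g1 = "A", g2 = "C"), phy2)
  expect_equal(mp2$score, 1L)
  expect_length(mp2$labelings, 2L)
  roots <- sort(vapply(mp2$labelings, function(l) l[["r"]], ""))
  expect_equal(roots, c("A", "C"))

  mp0 <- enumerate_mprs(c(g1 = "A", g2 = "A"), phy2)
  expect_equal(mp0$score, 0L)
  expect_length(mp0$labelings, 1L)
})

test_that("every enumerated labeling attains exactly the parsimony score", {
  set.seed(7)
  for (i in 1:25) {
    inst <- random_instance(n_tip = sample(4:7, 1), n_states = sample(2:4, 1))
    mp <- enumerate_mprs(inst$column, inst$phy)
    nev <- vapply(mp$labelings,
                  function(l) nrow(mpr_events(l, inst$phy)), 0L)
    expect_true(all(nev == mp$score), info = paste("instance", i))
    expect_false(any(duplicated(vapply(mp$labelings, paste, "", collapse = ""))))
    ## lower bound: distinct observed states - 1
    obs <- unique(inst$column[!inst$column %in% c("-", "X")])
    expect_gte(mp$score, length(obs) - 1L)
  }
})

test_that("DP event classification matches enumeration-derived sets", {
  set.seed(13)
  for (i in 1:40) {
    inst <- random_instance(n_tip = sample(3:7, 1), n_states = sample(2:5, 1))
    ps <- polarize_site(inst$column, inst$phy, site = 1)
    mp <- enumerate_mprs(inst$column, inst$phy)
    sets <- mpr_event_sets(mp, inst$phy)
    un <- ps$records[!ps$records$ambiguous, ]
    expect_setequal(paste(un$branch_id, un$source_aa, un$dest_aa),
                    sets$intersection)
    alt <- unique(paste(ps$alternatives$branch_id,
                        ps$alternatives$source_aa, ps$alternatives$dest_aa))
    expect_setequal(alt, setdiff(sets$union, sets$intersection))
    expect_equal(nrow(ps$records), mp$score)
  }
})

test_that("polarize_site handles the worked examples and masked sites", {
  ps <- polarize_site(five_leaf_column(), five_leaf_tree(), site = 3)
  expect_equal(nrow(ps$records), 1L)
  expect_false(ps$records$ambiguous)
  expect_equal(ps$records$branch_id, "n3")
  expect_equal(ps$records$source_aa, "A")
  expect_equal(ps$records$dest_aa, "C")

  phy2 <- ape::read.tree(text = "(g1:1,g2:1)r;")
  ps2 <- polarize_site(c(g1 = "A", g2 = "C"), phy2, site = 1)
  expect_equal(nrow(ps2$records), 1L)
  expect_true(ps2$records$ambiguous)
  expect_equal(ps2$records$n_alternatives, 2L)
  expect_equal(nrow(ps2$alternatives), 2L)

  expect_error(polarize_site(c(g1 = "A", g2 = "C"), phy2, site = 2,
                             mask = c(FALSE, TRUE)), "masked")
})

test_that("events flipping direction across the root are always ambiguous", {
  ## two sister pairs with different states: the single change can sit on
  ## either root child, with opposite directions
  phy <- ape::read.tree(text = "((a:1,b:1)x:1,(c:1,d:1)y:1)r;")
  ps <- polarize_site(c(a = "A", b = "A", c = "C", d = "C"), phy, site = 1)
  expect_true(all(ps$records$ambiguous))
  expect_setequal(ps$alternatives$branch_id, c("x", "y"))
})

test_that("polarize_family totals and context tagging behave", {
  st <- species_tree(ape::read.tree(text = "(A:1,B:1);"))
  gt <- gene_tree(ape::read.tree(text = "(((A_1:1,A_2:1)d:1,B_1:1)s:1,B_2:1)r;"))
  rt <- lca_reconcile(gt, st)
  ## identical sequences: nothing to report
  base <- paste(rep("M", 10), collapse = "")
  aln0 <- family_alignment(setNames(rep(base, 4), gt$phy$tip.label), "f0")
  p0 <- polarize_family(aln0, rt)
  expect_equal(p0$summary$n_substitutions, 0L)
  expect_equal(p0$summary$n_sites_with_substitution, 0L)
  ## one variable site among 100: A_1 alone derived at site 1
  seqs <- setNames(c(paste0("W", strrep("M", 99)), strrep("M", 100),
                     strrep("M", 100), strrep("M", 100)),
                   c("A_1", "A_2", "B_1", "B_2"))
  p1 <- polarize_family(family_alignment(seqs, "f1"), rt)
  expect_equal(p1$summary$n_substitutions, 1L)
  expect_equal(p1$summary$n_sites_with_substitution, 1L)
  expect_equal(p1$summary$n_sites_unmasked, 100L)
  r <- p1$records
  expect_false(r$ambiguous)
  expect_equal(r$branch_id, "A_1")
  expect_equal(paste0(r$source_aa, r$dest_aa), "MW")
  expect_equal(r$context, "duplicated")
  ## A_1 sits in clade 1 of duplication d, and of the root duplication r
  ## (B_1 and B_2 make the root a duplication under LCA mapping)
  expect_equal(r$clade_ids, "d.1,r.1")
})

test_that("unambiguous records on simulated data are a subset of the truth", {
  for (seed in c(21, 22)) {
    sim <- sim_family_fixture(seed, subst_rate = 0.02, seq_length = 200)
    pol <- polarize_family(sim$alignment, sim$rtree)
    un <- pol$records[!pol$records$ambiguous, ]
    truth_keys <- paste(sim$truth$events$site, sim$truth$events$branch_id,
                        sim$truth$events$source_aa, sim$truth$events$dest_aa)
    got_keys <- paste(un$site, un$branch_id, un$source_aa, un$dest_aa)
    ## at low rates nearly every true event is a single change on its branch;
    ## every unambiguous call must be a true event
    expect_true(all(got_keys %in% truth_keys))
    expect_lte(pol$summary$n_unambiguous, pol$summary$n_substitutions)
  }
})
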