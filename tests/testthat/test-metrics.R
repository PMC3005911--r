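test_that("flux D follows (C-R)/(C+R) on hand-computed cases", {
  ft <- flux_table(make_records(c("A", "A", "C"), c("C", "C", "A")))
  aa <- setNames(ft$aa$D, ft$aa$aa)
  expect_equal(unname(aa["C"]), 1 / 3)
  expect_equal(unname(aa["A"]), -1 / 3)
  expect_equal(ft$pair_D["A", "C"], 1 / 3) # net gain toward C
  expect_equal(ft$n_substitutions, 3)

  ## balanced reciprocal counts: all defined D are 0
  ft0 <- flux_table(make_records(c("A", "C", "W", "M"), c("C", "A", "M", "W")))
  expect_true(all(ft0$aa$D[!is.na(ft0$aa$D)] == 0))

  ## single record: boundary values
  ft1 <- flux_table(make_records("A", "C"))
  aa1 <- setNames(ft1$aa$D, ft1$aa$aa)
  expect_equal(unname(aa1[c("C", "A")]), c(1, -1))

  ## empty selection: everything undefined
  fte <- flux_table(make_records("A", "C"), branches = character(0))
  expect_true(all(is.na(fte$aa$D)))
  expect_equal(fte$n_substitutions, 0)
})

test_that("flux conservation and pairwise antisymmetry hold exactly", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    pairs <- t(replicate(n, sample(aa_alphabet(), 2)))
    recs <- make_records(pairs[, 1], pairs[, 2])
    ## make a few records ambiguous with alternatives
    amb <- sample(n, min(3, n))
    recs$ambiguous[amb] <- TRUE
    recs$branch_id[amb] <- NA
    alts <- do.call(rbind, lapply(amb, function(j) {
      k <- sample(2:3, 1)
      data.frame(record_id = recs$record_id[j], family_id = "fam",
                 site = recs$site[j], branch_id = sprintf("ab%d", seq_len(k)),
                 source_aa = sample(aa_alphabet(), k, replace = TRUE),
                 dest_aa = sample(aa_alphabet(), k, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    alts <- alts[alts$source_aa != alts$dest_aa, ]
    recs$source_aa[amb] <- NA; recs$dest_aa[amb] <- NA
    for (w in c("split", "unit")) {
      ft <- flux_table(recs, alts, weighting = w)
      expect_equal(sum(ft$aa$C), sum(ft$aa$R))
      expect_equal(sum(ft$aa$C), ft$n_substitutions)
      pd <- ft$pair_D
      expect_equal(pd[upper.tri(pd)], -t(pd)[upper.tri(pd)])
    }
  }
})

test_that("delta polarity is signed, antisymmetric, and unambiguous-only", {
  sc <- aa_scales()
  dp <- delta_polarity(make_records(c("A", "D"), c("D", "A")), sc)
  expect_gt(dp$delta_polarity[1], 0) # Asp is more polar than Ala
  expect_equal(sum(dp$delta_polarity), 0)
  expect_equal(dp$abs_delta_polarity[1], dp$abs_delta_polarity[2])
  expect_equal(dp$delta_polarity[1],
               unname(sc$polarity["D"] - sc$polarity["A"]))
  bad <- make_records("A", "C")
  bad$ambiguous <- TRUE
  expect_error(delta_polarity(bad, sc), "unambiguous")
})

test_that("exchangeability is a direction-sensitive matrix lookup", {
  sc <- aa_scales()
  recs <- make_records(c("L", "C"), c("I", "W"))
  ex <- exchangeability(recs, sc)
  expect_equal(ex$exchangeability,
               c(sc$exchangeability["L", "I"], sc$exchangeability["C", "W"]),
               ignore_attr = TRUE)
  expect_gt(ex$exchangeability[1], ex$exchangeability[2]) # L->I conservative
  bad <- recs; bad$ambiguous <- TRUE
  expect_error(exchangeability(bad, sc), "unambiguous")
})

test_that("scale loading fails fast on incomplete tables", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("aa\tpolarity", "A\t8.1"), f)
  expect_error(aa_scales(polarity_file = f), "20 amino acids")
  g <- withr::local_tempfile(fileext = ".tsv")
  m <- synthetic_exchangeability()
  m["A", "C"] <- NA
  utils::write.table(m, g, sep = "\t", quote = FALSE)
  expect_error(aa_scales(exchangeability_file = g), "missing off-diagonal")
})

test_that("family Ka/Ks follows the substitutions/sites/Ks definitions", {
  ## 4 substitutions on 100 unmasked sites with total Ks 0.5 -> Ka/Ks 0.08
  st <- species_tree(ape::read.tree(text = "((A:1,B:1):1,C:1);"))
  gt <- gene_tree(ape::read.tree(
    text = "((A_1:0.125,B_1:0.125)s:0.125,C_1:0.125)r;"))
  rt <- lca_reconcile(gt, st)
  part <- partition_branches(rt)
  recs <- make_records(c("A", "C", "W", "M"), c("C", "A", "M", "W"),
                       branch = c("A_1", "B_1", "s", "C_1"))
  mask <- rep(FALSE, 100)
  fs <- family_ka_ks(recs, data.frame(), part, mask, rt)
  whole <- fs[fs$class == "whole", ]
  expect_equal(whole$ka, 0.04)
  expect_equal(whole$ks_sum, 0.5)
  expect_equal(whole$ka_ks, 0.08)
  ## no substitutions: Ka = 0 and Ka/Ks = 0
  fs0 <- family_ka_ks(make_records(character(), character()),
                      data.frame(), part, mask, rt)
  expect_equal(fs0$ka[fs0$class == "whole"], 0)
  expect_equal(fs0$ka_ks[fs0$class == "whole"], 0)
  ## family without duplication: duplicated-class fields are NA
  expect_true(is.na(fs$ka[fs$class == "duplicated"]))
  expect_true(all(fs$class[!is.na(fs$ka)] %in%
                    c("whole", "single_copy_no_dup_family")))
})

test_that("clade statistics and asymmetry follow A = |x1-x2|/(x1+x2)", {
  gt <- gene_tree(ape::read.tree(
    text = "((A_1:0.5,A_2:0.5)d:1,B_1:1)r;"))
  rt <- lca_reconcile(gt, two_species_tree())
  dups <- extract_duplications(rt)
  mk <- function(n1, n2) {
    br <- c(rep("A_1", n1), rep("A_2", n2))
    make_records(rep("A", n1 + n2), rep("C", n1 + n2), branch = br)
  }
  ## equal rates (clade Ks both 0.5)
  cs <- clade_stats(dups, mk(3, 3), aaflux:::.empty_alternatives())
  expect_equal(cs$A_rate, 0)
  ## rates 0.3 vs 0.1 after Ks normalisation: counts 3 vs 1 on Ks 0.5 each
  cs2 <- clade_stats(dups, mk(3, 1), aaflux:::.empty_alternatives())
  expect_equal(cs2$A_rate, 0.5)
  ## one empty clade
  cs3 <- clade_stats(dups, mk(4, 0), aaflux:::.empty_alternatives())
  expect_equal(cs3$A_rate, 1)
  expect_equal(cs3$clade2_n_total, 0)
})

test_that("category aggregation is unweighted with per-paralog multiplicity", {
  fs <- data.frame(family_id = c("f1", "f2", "f3"),
                   ka_ks = c(0.1, 0.3, 0.9), stringsAsFactors = FALSE)
  ann <- data.frame(family_id = c("f1", "f2", "f3", "f3"),
                    category = c("enzyme", "enzyme", "receptor", "receptor"),
                    stringsAsFactors = FALSE)
  agg <- category_aggregate(fs, ann, "ka_ks")
  expect_equal(agg$mean[agg$category == "enzyme"], 0.2)
  expect_equal(agg$n[agg$category == "receptor"], 2L) # two annotated paralogs
  expect_equal(agg$se[agg$category == "receptor"], 0)
  ## unannotated family f4 is excluded silently
  fs2 <- rbind(fs, data.frame(family_id = "f4", ka_ks = 5))
  expect_equal(category_aggregate(fs2, ann, "ka_ks"), agg)
  expect_error(category_aggregate(fs, ann, "ka_ks", vocabulary = "enzyme"),
               "receptor")
})

test_that("flux correlation inputs cover 190 pairs and drop undefined ones", {
  ## one record per ordered pair: every unordered pair defined
  combs <- t(utils::combn(aa_alphabet(), 2))
  recs <- make_records(c(combs[, 1], combs[, 2]), c(combs[, 2], combs[, 1]))
  ft <- flux_table(recs)
  fc <- flux_correlations(ft, "polarity")
  expect_equal(nrow(fc), 190L)
  expect_equal(attr(fc, "n_dropped"), 0L)
  ## sparse data: undefined pairs dropped and counted
  ft2 <- flux_table(make_records("A", "C"))
  fc2 <- flux_correlations(ft2, "polarity")
  expect_equal(nrow(fc2), 1L)
  expect_equal(attr(fc2, "n_dropped"), 189L)
  ## covariate with missing amino acids errors, naming them
  expect_error(flux_correlations(ft, "frequency", values = c(A = 0.1)), "C")
  ## constant covariate flagged
  const <- setNames(rep(1, 20), aa_alphabet())
  fc3 <- flux_correlations(ft, "frequency", values = const)
  expect_true(attr(fc3, "constant_covariate"))
})

test_that("amino-acid frequencies sum to one and respect the mask", {
  aln <- family_alignment(c(g1 = "AAC--W", g2 = "AACMMW"), "f")
  fr <- aa_frequencies(list(aln))
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["M"]), 0) # masked columns excluded
  fr2 <- aa_frequencies(list(aln), masked = FALSE)
  expect_gt(fr2[["M"]], 0)
})
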