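cfg <- pipeline_config()

make_lib <- function(seqs, shs, fams) {
  reference_library(
    data.frame(seq_id = names(seqs), sh_id = shs, sequence = unname(seqs),
               stringsAsFactors = FALSE),
    data.frame(sh_id = unique(shs), name = unique(shs), kind = "formal",
               family = fams[match(unique(shs), shs)], stringsAsFactors = FALSE))
}

test_that("an identical query sits at zero branch length beside its reference", {
  set.seed(61)
  a <- random_dna_string(200); b <- mutate_string(a, 30)
  lib <- make_lib(c(r1 = a, r2 = b), c("SH_A", "SH_B"), c("Fam", "Fam"))
  ft <- build_family_tree("Fam", c(q1 = a), lib, config = cfg)
  expect_s3_class(ft$tree, "phylo")
  q_edge <- ft$tree$edge.length[ft$tree$edge[, 2] == which(ft$tree$tip.label == "q1")]
  expect_equal(q_edge, 0, tolerance = 1e-8)
})

test_that("an external newick passes through topologically identical", {
  set.seed(62)
  seqs <- setNames(replicate(4, random_dna_string(120)), paste0("r", 1:4))
  lib <- make_lib(seqs, paste0("SH_", 1:4), rep("Fam", 4))
  nwk <- "((r1:1,r2:1):1,(r3:1,r4:1):1);"
  ft <- build_family_tree("Fam", character(0), lib, external_tree = nwk, config = cfg)
  expect_equal(phangorn::RF.dist(ape::unroot(ft$tree), ape::unroot(read_newick(nwk))), 0)
  # tips that do not reconcile error out
  expect_error(build_family_tree("Fam", character(0), lib,
                                 external_tree = "((r1:1,r2:1):1,(r3:1,rX:1):1);",
                                 config = cfg),
               "reconcile")
})

test_that("NJ recovers the generating topology for well-separated families", {
  p <- sim_params(n_families = 1, species_per_family = 8, family_depth = 0.1,
                  regional_coverage = 1, refs_per_species = c(1, 1),
                  n_sites = 1, species_per_site = 8, core_set_size = 2,
                  site_unique_fraction = 0, rng_seed = 63)
  pool <- simulate_species_pool(p, cfg)
  libs <- build_libraries(pool, p)
  fam <- pool$species$family[1]
  ft <- build_family_tree(fam, character(0), libs$regional, config = cfg)
  inferred <- ft$tree
  # relabel reference tips by their SH to compare against the generating tree
  inferred$tip.label <- unname(ft$ref_tips[inferred$tip.label])
  expect_equal(phangorn::RF.dist(ape::unroot(inferred),
                                 ape::unroot(pool$trees[[fam]])), 0)
})

test_that("monophyly evaluation matches the textbook clade configurations", {
  ft1 <- ftree_fixture("((a1:1,a2:1):1,(b1:1,b2:1):1);",
                       c(a1 = "SH_A", a2 = "SH_A", b1 = "SH_B", b2 = "SH_B"))
  expect_true(all(evaluate_sh_monophyly(ft1)))
  ft2 <- ftree_fixture("((a1:1,b1:1):1,(a2:1,b2:1):1);",
                       c(a1 = "SH_A", a2 = "SH_A", b1 = "SH_B", b2 = "SH_B"))
  expect_false(any(evaluate_sh_monophyly(ft2)))
  # query tips are ignored when judging reference monophyly
  ft3 <- ftree_fixture("((a1:1,(q1:1,a2:1):1):1,b1:2);",
                       c(a1 = "SH_A", a2 = "SH_A", b1 = "SH_B"), "q1")
  expect_true(evaluate_sh_monophyly(ft3)[["SH_A"]])
  # single-sequence SHs are trivially monophyletic
  expect_true(evaluate_sh_monophyly(ft3)[["SH_B"]])
})

test_that("monophyly assignment follows the smallest reference-containing clade", {
  ft <- ftree_fixture("((q:1,a1:1):1,(a2:1,b1:1):1);",
                      c(a1 = "SH_A", a2 = "SH_A", b1 = "SH_B"), "q")
  res <- assign_by_monophyly(ft)
  expect_true(res$success)
  expect_equal(res$assigned_sh, "SH_A")
  # a smallest clade holding two SHs leaves the query unassigned
  ft2 <- ftree_fixture("(q:3,(a1:1,b1:1):1);",
                       c(a1 = "SH_A", b1 = "SH_B"), "q")
  res2 <- assign_by_monophyly(ft2)
  expect_false(res2$success)
  # nested queries both resolve to the enclosing single-SH clade
  ft3 <- ftree_fixture("((q1:1,(q2:1,a1:1):1):1,b1:3);",
                       c(a1 = "SH_A", b1 = "SH_B"), c("q1", "q2"))
  res3 <- assign_by_monophyly(ft3)
  expect_equal(unname(res3$assigned_sh[order(res3$otu_id)]), c("SH_A", "SH_A"))
  expect_error(assign_by_monophyly(
    lichid:::new_family_tree("F", read_newick("(q1:1,q2:1);"),
                             setNames(character(0), character(0)), c("q1", "q2"))),
    "no reference tips")
})

test_that("assignment agrees with exhaustive clade enumeration on random trees", {
  set.seed(64)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    tree <- ape::rtree(n, rooted = TRUE)
    tree$tip.label <- paste0("t", seq_len(n))
    n_q <- sample(1:(n - 2), 1)
    queries <- sample(tree$tip.label, n_q)
    refs <- setdiff(tree$tip.label, queries)
    ref_tips <- setNames(paste0("SH_", sample(1:3, length(refs), replace = TRUE)), refs)
    ft <- lichid:::new_family_tree("F", tree, ref_tips, queries)
    mine <- assign_by_monophyly(ft)
    orc <- oracle_monophyly_assign(tree, ref_tips, queries)
    expect_identical(setNames(mine$assigned_sh, mine$otu_id)[queries], orc)
  }
})

test_that("assignment is invariant to tip rotations", {
  ft <- ftree_fixture("((q:1,a1:1):1,(a2:1,b1:1):1);",
                      c(a1 = "SH_A", a2 = "SH_A", b1 = "SH_B"), "q")
  rot <- ft
  rot$tree <- ape::rotateConstr(ft$tree, rev(ft$tree$tip.label))
  expect_equal(assign_by_monophyly(rot)$assigned_sh,
               assign_by_monophyly(ft)$assigned_sh)
})

test_that("OTUs collapse into SH entries per the clade + identity rules", {
  set.seed(65)
  a <- random_dna_string(200); b <- mutate_string(a, 30)
  lib <- make_lib(c(r1 = a, r2 = b), c("SH_A", "SH_B"), c("Fam", "Fam"))
  # three OTUs assigned to one SH collapse to a single entry
  otus <- c(q1 = a, q2 = mutate_string(a, 1), q3 = mutate_string(a, 1))
  ft <- build_family_tree("Fam", otus, lib, config = cfg)
  asg <- assign_by_monophyly(ft)
  expect_true(all(asg$success))
  entries <- collapse_to_species_hypotheses(asg, list(Fam = ft), otus, 0.99, cfg)
  expect_equal(nrow(entries), 1L)
  expect_equal(entries$sh_id, "SH_A")
  expect_equal(entries$n_otus, 3L)
  # two unassigned OTUs at 99.5% identity forming their own clade merge
  far <- mutate_string(a, 60) # an uncovered species
  otus2 <- c(q1 = far, q2 = mutate_string(far, 1))
  ft2 <- build_family_tree("Fam", otus2, lib, config = cfg)
  asg2 <- assign_by_monophyly(ft2)
  expect_false(any(asg2$success))
  entries2 <- collapse_to_species_hypotheses(asg2, list(Fam = ft2), otus2, 0.99, cfg)
  expect_equal(nrow(entries2), 1L)
  expect_true(is.na(entries2$sh_id))
  expect_equal(entries2$n_otus, 2L)
  expect_false(entries2$identified)
  # zero OTUs give an empty inventory
  empty <- collapse_to_species_hypotheses(
    data.frame(otu_id = character(0), assigned_sh = character(0),
               success = logical(0)), list(), character(0), 0.99, cfg)
  expect_equal(nrow(empty), 0L)
})
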