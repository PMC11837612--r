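test_that("the species-count filter partitions at the >2-species boundary", {
  tab <- read_orthogroups(write_fixture_og())
  flt <- filter_min_species(tab, min_species = 3)
  # OG1 (3 sp) retained; OG4 (3 sp) retained; OG2 (4), OG6 (5) retained;
  # OG3 (1 sp) and OG5 (2 sp) excluded
  expect_setequal(flt$retained$orthogroups, c("OG1", "OG2", "OG4", "OG6"))
  expect_setequal(flt$excluded, c("OG3", "OG5"))
  expect_equal(length(flt$retained$orthogroups) + length(flt$excluded),
               length(tab$orthogroups))
  expect_error(filter_min_species(tab, 0), "min_species")
})

test_that("MRCA of trivial sets behaves (root, single leaf, unknown leaf)", {
  phy <- fixture_tree()
  expect_equal(mrca_node(phy, leaves(phy)), phy$labels[phy$root])
  expect_equal(mrca_node(phy, "spC"), "spC")
  expect_error(mrca_node(phy, c("spA", "nope")), "nope")
  expect_error(mrca_node(phy, character(0)), "non-empty")
})

test_that("MRCA equals the root-path-intersection oracle on random trees", {
  set.seed(101)
  for (rep in 1:40) {
    phy <- random_phylogeny(sample(4:60, 1))
    for (s in 1:10) {
      leaf_set <- sample(leaves(phy), sample(seq_len(phy$n_tip), 1))
      expect_identical(mrca_node(phy, leaf_set), oracle_mrca(phy, leaf_set))
    }
  }
})

test_that("MRCA is monotone: adding leaves never yields a more recent node", {
  set.seed(202)
  phy <- random_phylogeny(40)
  for (rep in 1:50) {
    s1 <- sample(leaves(phy), sample(2:10, 1))
    s2 <- union(s1, sample(leaves(phy), sample(1:10, 1)))
    m1 <- mrca_node(phy, s1)
    m2 <- mrca_node(phy, s2)
    expect_true(is_ancestor(phy, m2, m1))
  }
})

test_that("gain assignment maps presence sets to their MRCA and partitions", {
  phy <- fixture_tree()
  tab <- read_orthogroups(write_fixture_og())
  flt <- filter_min_species(tab)
  gm <- assign_gains(phy, flt$retained)
  expect_equal(nrow(gm$assignments), length(flt$retained$orthogroups))
  expect_equal(sum(gm$node_counts), nrow(gm$assignments))
  # hand-checked: OG6 present everywhere -> root
  a <- setNames(gm$assignments$node, gm$assignments$orthogroup)
  expect_equal(unname(a["OG6"]), phy$labels[phy$root])
  # OG1 spans spA,spB,spC -> root (only node covering both clades)
  expect_equal(unname(a["OG1"]), oracle_mrca(phy, c("spA", "spB", "spC")))
  # each gain node is an ancestor of every present leaf
  pres <- presence_sets(flt$retained)
  for (og in names(pres)) {
    for (lf in pres[[og]])
      expect_true(is_ancestor(phy, a[[og]], lf))
  }
  expect_error(assign_gains(phy, orthogroup_table(
    list(OGx = list(spZ = "z1")), "spZ")), "spZ")
})

test_that("orthogroups_at extracts a stable sorted partition", {
  phy <- fixture_tree()
  tab <- read_orthogroups(write_fixture_og())
  gm <- assign_gains(phy, filter_min_species(tab)$retained)
  all_nodes <- c(leaves(phy), internal_nodes(phy))
  per_node <- lapply(all_nodes, orthogroups_at, gain_map = gm, phy = phy)
  expect_equal(sum(lengths(per_node)), nrow(gm$assignments))
  expect_true(all(vapply(per_node, function(x) !is.unsorted(x), logical(1))))
  expect_error(orthogroups_at(gm, "no_such_node", phy), "no_such_node")
})

test_that("simulated zero-loss families recover their gain node exactly", {
  st <- sim_species_tree(n_focal = 30, n_outgroup = 6, seed = 9)
  cfg <- sim_config(n_orthogroups = 80, loss_prob = 0, dup_lambda = 0.05,
                    seed = 9)
  sim <- simulate_families(st$phy, cfg)
  gm <- assign_gains(st$phy, sim$table)
  idx <- match(gm$assignments$orthogroup, sim$truth$orthogroup)
  expect_true(all(gm$assignments$node == sim$truth$gain_node[idx]))
})

test_that("with loss, inferred gains stay within the true gain subtree", {
  st <- sim_species_tree(n_focal = 30, n_outgroup = 6, seed = 10)
  cfg <- sim_config(n_orthogroups = 120, loss_prob = 0.15, dup_lambda = 0,
                    seed = 10)
  sim <- simulate_families(st$phy, cfg)
  gm <- assign_gains(st$phy, sim$table)
  idx <- match(gm$assignments$orthogroup, sim$truth$orthogroup)
  ok <- mapply(function(true_nd, inf_nd)
    is_ancestor(st$phy, true_nd, inf_nd),
    sim$truth$gain_node[idx], gm$assignments$node)
  expect_true(all(ok))
})

test_that("the alternative-annotation rescue demotes on strict thresholds", {
  qmap <- c(g1 = "OGa", g2 = "OGb", g3 = "OGc")
  hits <- data.frame(
    query_id = c("g1", "g2", "g3"),
    subject_id = c("t1", "t2", "t3"),
    pident = c(30, 25.0, 40),          # 25.0 is NOT above 25
    evalue = c(1e-6, 1e-9, 1e-6),
    qcov = c(65, 90, 59.9),            # g3 fails coverage
    scov = c(70, 90, 90),
    taxon_class = "focal_clade", stringsAsFactors = FALSE)
  res <- rescue_against_alternative_annotation(
    c("OGa", "OGb", "OGc", "OGd"), hits, qmap)
  expect_equal(res$demoted, "OGa")
  expect_setequal(res$confirmed, c("OGb", "OGc", "OGd"))
  expect_length(intersect(res$confirmed, res$demoted), 0)
})

test_that("rescue partition holds on random fixtures", {
  set.seed(5)
  for (rep in 1:20) {
    n <- 30
    qmap <- setNames(paste0("OG", sample(10, 50, replace = TRUE)),
                     paste0("q", 1:50))
    hits <- random_hit_table(n)
    cands <- paste0("OG", 1:10)
    res <- rescue_against_alternative_annotation(cands, hits, qmap)
    expect_setequal(c(res$confirmed, res$demoted), cands)
    expect_length(intersect(res$confirmed, res$demoted), 0)
  }
})
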