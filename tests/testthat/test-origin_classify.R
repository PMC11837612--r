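mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(query_id = r[[1]], subject_id = r[[2]],
               pident = as.numeric(r[[3]]), evalue = as.numeric(r[[4]]),
               qcov = as.numeric(r[[5]]), scov = as.numeric(r[[6]]),
               taxon_class = r[[7]], stringsAsFactors = FALSE)))
}

test_that("hit filtering enforces the strict-identity regime at the boundary", {
  h <- mk_hits(
    list("q", "s1", 30,   1e-6, 65, 70,   "other_metazoa"),  # pass
    list("q", "s2", 30,   1e-6, 65, 59.9, "other_metazoa"),  # scov fails
    list("q", "s3", 25.0, 1e-6, 90, 90,   "other_metazoa"),  # 25 not > 25
    list("q", "s4", 25.1, 1e-5, 60, 60,   "other_metazoa"),  # boundary pass
    list("q", "s5", 30,   2e-5, 90, 90,   "other_metazoa"))  # evalue fails
  kept <- filter_hits(h)
  expect_equal(kept$subject_id, c("s1", "s4"))
  # linking regime keeps identity == threshold
  kept_ge <- filter_hits(h, identity_strict = FALSE)
  expect_true("s3" %in% kept_ge$subject_id)
  expect_error(filter_hits(h, min_identity = 120), "0, 100")
})

test_that("filtering matches the brute-force predicate on random records", {
  set.seed(77)
  h <- random_hit_table(1000)
  # sprinkle exact boundary values
  h$pident[1:50] <- 25
  h$qcov[26:75] <- 60
  h$scov[51:100] <- 60
  h$evalue[76:125] <- 1e-5
  for (strict in c(TRUE, FALSE)) {
    kept <- filter_hits(h, 1e-5, 25, 60, 60, identity_strict = strict)
    want <- oracle_filter(h, 1e-5, 25, 60, 60, strict)
    expect_equal(kept$subject_id, h$subject_id[want])
  }
})

test_that("filtering is monotone: tightening thresholds never adds hits", {
  set.seed(78)
  h <- random_hit_table(300)
  base <- filter_hits(h, 1e-4, 20, 50, 50)
  tighter <- list(
    filter_hits(h, 1e-6, 20, 50, 50),
    filter_hits(h, 1e-4, 30, 50, 50),
    filter_hits(h, 1e-4, 20, 70, 50),
    filter_hits(h, 1e-4, 20, 50, 70))
  for (t in tighter)
    expect_true(all(t$subject_id %in% base$subject_id))
})

test_that("the origin decision table is exhaustive over evidence combinations", {
  qmap <- c(g1 = "OG1")
  met <- mk_hits(list("g1", "m1", 40, 1e-10, 80, 80, "other_metazoa"))
  non <- mk_hits(list("g1", "b1", 40, 1e-10, 80, 80, "non_metazoa"))
  dom <- data.frame(gene_id = "g1", accession = "PF00001", evalue = 1e-6,
                    stringsAsFactors = FALSE)
  none_h <- met[0, ]; none_d <- dom[0, ]
  cases <- expand.grid(has_met = c(FALSE, TRUE), has_non = c(FALSE, TRUE),
                       has_dom = c(FALSE, TRUE))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    call <- classify_origin("OG1", qmap,
                            if (cs$has_dom) dom else none_d,
                            if (cs$has_met) met else none_h,
                            if (cs$has_non) non else none_h)
    want <- if (cs$has_met || cs$has_dom) "duplication_divergence"
            else if (cs$has_non) "hgt" else "de_novo_candidate"
    expect_equal(call$label, want,
                 info = paste("met", cs$has_met, "non", cs$has_non,
                              "dom", cs$has_dom))
  }
  # domain-alone evidence can be switched off
  call <- classify_origin("OG1", qmap, dom, none_h, none_h,
                          domain_as_duplication = FALSE)
  expect_equal(call$label, "de_novo_candidate")
})

test_that("focal-clade leakage into classification inputs is an error", {
  qmap <- c(g1 = "OG1")
  leak <- mk_hits(list("g1", "x1", 40, 1e-10, 80, 80, "focal_clade"))
  expect_error(classify_origin("OG1", qmap, NULL, leak, leak[0, ]),
               "focal")
})

test_that("low-coverage hits are annotated partial but still counted", {
  qmap <- c(g1 = "OG1")
  met <- mk_hits(list("g1", "m1", 40, 1e-10, 30, 80, "other_metazoa"))
  call <- classify_origin("OG1", qmap, NULL, met, met[0, ])
  expect_equal(call$label, "duplication_divergence")
  expect_equal(call$n_partial_hits, 1L)
})

test_that("orthogroup linking honours the equal-or-above rule and finds components", {
  qmap <- c(p1 = "OGseed", p2 = "OGb", p3 = "OGc", p4 = "OGd")
  hits <- mk_hits(
    list("p1", "p2", 25.0, 1e-20, 60, 60, "focal_clade"),  # links (>=)
    list("p2", "p3", 80,   1e-20, 90, 90, "focal_clade"),  # chains
    list("p1", "p4", 24.9, 1e-20, 90, 90, "focal_clade"))  # below threshold
  links <- link_orthogroups("OGseed", hits, qmap)
  expect_setequal(links$component, c("OGseed", "OGb", "OGc"))
  expect_setequal(links$linked, c("OGb", "OGc"))
  # no passing hits: component is the seed alone
  links0 <- link_orthogroups("OGd", hits[3, ], qmap, min_identity = 99)
  expect_equal(links0$component, "OGd")
  expect_error(link_orthogroups("OGmissing", hits, qmap), "OGmissing")
})

test_that("linking equals brute-force union-find on random hit graphs", {
  set.seed(303)
  for (rep in 1:15) {
    n_og <- 12
    genes <- paste0("g", 1:60)
    qmap <- setNames(paste0("OG", sample(n_og, 60, replace = TRUE)), genes)
    h <- random_hit_table(80)
    h$query_id <- sample(genes, 80, replace = TRUE)
    h$subject_id <- sample(genes, 80, replace = TRUE)
    pass <- h$pident >= 25 & h$qcov >= 60 & h$scov >= 60
    want <- oracle_component("OG1", qmap[h$query_id[pass]],
                             qmap[h$subject_id[pass]],
                             paste0("OG", 1:n_og))
    got <- link_orthogroups("OG1", h, qmap, subject_map = qmap)
    expect_setequal(got$component, want)
    # seed-independence within a component
    for (other in setdiff(got$component, "OG1")) {
      alt <- link_orthogroups(other, h, qmap, subject_map = qmap)
      expect_setequal(alt$component, got$component)
    }
  }
})

test_that("mode summaries partition each node's gains", {
  phy <- fixture_tree()
  tab <- read_orthogroups(write_fixture_og())
  gm <- assign_gains(phy, filter_min_species(tab)$retained)
  qmap <- setNames(gm$assignments$orthogroup, paste0("q", seq_len(nrow(gm$assignments))))
  # plant one call per retained orthogroup
  calls <- classify_origin(gm$assignments$orthogroup,
                           setNames(names(qmap), names(qmap))[0],
                           NULL, NULL, NULL)
  expect_true(all(calls$label == "de_novo_candidate"))
  msum <- summarize_modes(calls, gm)
  per_node <- tapply(msum$count, msum$node, sum)
  expect_equal(unname(per_node[names(gm$node_counts)]),
               unname(gm$node_counts))
  # an uncalled orthogroup in the summary is an error
  bad <- calls
  bad$orthogroup[1] <- "OG_unmapped"
  expect_error(summarize_modes(bad, gm), "OG_unmapped")
  # empty call set -> empty table
  expect_equal(nrow(summarize_modes(calls[0, ], gm)), 0L)
})
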