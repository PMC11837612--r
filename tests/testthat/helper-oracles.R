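# Independent brute-force oracles, kept deliberately separate from the
# package's own algorithms.

# MRCA by root-path intersection: list each leaf's path to the root,
# intersect, take the deepest shared node.
oracle_mrca <- function(phy, leaf_set) {
  path_to_root <- function(label) {
    x <- unname(phy$index[label])
    p <- x
    while (phy$parent[x] != 0L) { x <- phy$parent[x]; p <- c(p, x) }
    p
  }
  shared <- Reduce(intersect, lapply(leaf_set, path_to_root))
  phy$labels[shared[which.max(phy$depth[shared])]]
}

# hit-filter predicate applied record by record
oracle_filter <- function(hits, max_e, min_id, min_q, min_s, strict) {
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    id_ok <- if (strict) h$pident > min_id else h$pident >= min_id
    keep[i] <- h$evalue <= max_e && id_ok && h$qcov >= min_q && h$scov >= min_s
  }
  keep
}

# connected components by union-find over orthogroup-level edges
oracle_component <- function(seed, edges_a, edges_b, all_nodes) {
  parent <- stats::setNames(all_nodes, all_nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_along(edges_a)) {
    ra <- find(edges_a[i]); rb <- find(edges_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  rs <- find(seed)
  sort(all_nodes[vapply(all_nodes, function(v) find(v) == rs, logical(1))])
}

# Dunn one-vs-rest z, written from scratch (sorting-based ranks, rle tie
# counts) rather than via rank()/split()
oracle_dunn_z <- function(matrix) {
  x <- as.numeric(t(matrix))
  N <- length(x)
  ord <- order(x)
  r <- numeric(N)
  sorted <- x[ord]
  i <- 1L; pos <- 1L
  runs <- rle(sorted)
  for (len in runs$lengths) {
    r[ord[pos:(pos + len - 1L)]] <- mean(pos:(pos + len - 1L))
    pos <- pos + len
  }
  S <- N * (N + 1) / 12 - sum(runs$lengths^3 - runs$lengths) / (12 * (N - 1))
  k <- nrow(matrix); n <- ncol(matrix)
  vapply(seq_len(k), function(i) {
    idx <- ((i - 1L) * n + 1L):(i * n)
    ri <- mean(r[idx]); rr <- mean(r[-idx])
    (ri - rr) / sqrt(S * (1 / n + 1 / (N - n)))
  }, numeric(1))
}

# tie-corrected Kruskal-Wallis H from the textbook formula
oracle_kw_H <- function(matrix) {
  x <- as.numeric(t(matrix))
  g <- rep(seq_len(nrow(matrix)), each = ncol(matrix))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# small in-code fixture: 5 species, 6 orthogroups
fixture_og_lines <- function() {
  c("Orthogroup\tspA\tspB\tspC\tspD\tspE",
    "OG1\ta1, a2\tb1\tc1\t\t",
    "OG2\t\tb2\tc2\td1\te1",
    "OG3\ta3\t\t\t\t",
    "OG4\ta4\tb3\t\t\te2",
    "OG5\t\t\tc3\td2\t",
    "OG6\ta5\tb4\tc4\td3\te3")
}

write_fixture_og <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(fixture_og_lines(), path)
  path
}

fixture_tree <- function() {
  # ((spA,spB),(spC,(spD,spE))); rooted, no internal labels
  p <- tempfile(fileext = ".nwk")
  writeLines("((spA,spB),(spC,(spD,spE)));", p)
  read_newick(p)
}

random_phylogeny <- function(n) as_phylogeny(ape::rtree(n))

random_hit_table <- function(n, classes = c("other_metazoa", "non_metazoa")) {
  data.frame(
    query_id = paste0("q", sample(50, n, replace = TRUE)),
    subject_id = paste0("s", seq_len(n)),
    pident = round(stats::runif(n, 15, 40), 1),
    evalue = 10^stats::runif(n, -10, -2),
    qcov = round(stats::runif(n, 40, 80), 1),
    scov = round(stats::runif(n, 40, 80), 1),
    taxon_class = sample(classes, n, replace = TRUE),
    stringsAsFactors = FALSE)
}
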