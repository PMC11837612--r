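#' Filter orthogroups by presence-set size
#'
#' Taxonomically restricted families are only dated if they are present in
#' more than two species (default `min_species = 3`), since one- and
#' two-species groups carry too little signal to place on the tree.
#'
#' @param table an [orthogroup_table()].
#' @param min_species minimum number of species with at least one copy.
#' @return list with elements `retained` (an `orthogroup_table`) and
#'   `excluded` (character vector of orthogroup IDs).
#' @export
filter_min_species <- function(table, min_species = 3L) {
  if (min_species < 1L) stop("min_species must be >= 1")
  n_sp <- rowSums(table$counts > 0L)
  keep <- names(n_sp)[n_sp >= min_species]
  excl <- setdiff(table$orthogroups, keep)
  retained <- orthogroup_table(table$genes[keep], table$species)
  list(retained = retained, excluded = excl)
}

#' Most recent common ancestor of a leaf set
#'
#' The deepest node whose leaf descendants contain every leaf in
#' `leaf_set`.  Computed by folding pairwise lowest-common-ancestor
#' queries (ascend to equal depth, then climb together) over the set; a
#' single leaf is its own MRCA.
#'
#' @param phy a [as_phylogeny()] object.
#' @param leaf_set non-empty character vector of leaf names.
#' @return the MRCA's node ID (a leaf name or internal label).
#' @export
mrca_node <- function(phy, leaf_set) {
  if (length(leaf_set) == 0L) stop("leaf_set must be non-empty")
  unknown <- setdiff(leaf_set, leaves(phy))
  if (length(unknown) > 0L)
    stop("unknown leaf/leaves: ", paste(unknown, collapse = ", "))
  nodes <- unname(phy$index[unique(leaf_set)])
  parent <- phy$parent; depth <- phy$depth
  a <- nodes[1L]
  for (b in nodes[-1L]) {
    while (depth[a] > depth[b]) a <- parent[a]
    while (depth[b] > depth[a]) b <- parent[b]
    while (a != b) { a <- parent[a]; b <- parent[b] }
  }
  phy$labels[a]
}

#' Assign a gain node to every orthogroup
#'
#' The node of origin of each family is taken, parsimoniously, as the MRCA
#' of all species possessing at least one copy.  Gains are reported on
#' nodes; equivalently, a gain at node X dates the family to the branch
#' leading to X.
#'
#' @param phy a [as_phylogeny()] object whose leaf set covers the table's
#'   species roster.
#' @param table an (already filtered) [orthogroup_table()].
#' @return an object of class `gain_map`: list with `assignments`
#'   (data.frame `orthogroup`, `node`, `n_species`), `node_counts` (named
#'   integer vector over all nodes with at least one gain) and `excluded`
#'   (orthogroups with empty presence sets, skipped).
#' @export
assign_gains <- function(phy, table) {
  missing_sp <- setdiff(table$species, leaves(phy))
  if (length(missing_sp) > 0L)
    stop("species in table absent from tree: ",
         paste(missing_sp, collapse = ", "))
  pres <- presence_sets(table)
  nonempty <- names(pres)[lengths(pres) > 0L]
  nodes <- vapply(pres[nonempty], function(sp) mrca_node(phy, sp),
                  character(1))
  assignments <- data.frame(orthogroup = nonempty,
                            node = unname(nodes),
                            n_species = unname(lengths(pres[nonempty])),
                            stringsAsFactors = FALSE)
  tab <- table(assignments$node)
  structure(list(assignments = assignments,
                 node_counts = stats::setNames(as.integer(tab), names(tab)),
                 excluded = setdiff(table$orthogroups, nonempty)),
            class = "gain_map")
}

#' @export
print.gain_map <- function(x, ...) {
  cat("gain_map: ", nrow(x$assignments), " orthogroups over ",
      length(x$node_counts), " nodes\n", sep = "")
  invisible(x)
}

#' Orthogroups gained at a node
#' @param gain_map a [assign_gains()] result.
#' @param node_id a node ID present in the phylogeny used for mapping.
#' @param phy optionally the phylogeny, to validate `node_id` against the
#'   full node set (otherwise only nodes carrying gains are known).
#' @return sorted character vector of orthogroup IDs (possibly empty).
#' @export
orthogroups_at <- function(gain_map, node_id, phy = NULL) {
  if (!is.null(phy)) {
    node_number(phy, node_id)  # errors on unknown node
  } else if (!node_id %in% gain_map$assignments$node &&
             !node_id %in% names(gain_map$node_counts)) {
    # without the tree we can only check against observed nodes; accept
    # unknown-but-plausible IDs as "no gains" only when phy is supplied
    stop("node '", node_id, "' carries no gains and no phylogeny was ",
         "supplied to validate it")
  }
  sort(gain_map$assignments$orthogroup[gain_map$assignments$node == node_id])
}

#' Cross-check candidate clade-specific orthogroups against an alternative
#' annotation
#'
#' Families that look specific to a clade may simply be missing from the
#' outgroups' predicted proteomes.  Candidates with at least one passing
#' hit against an alternative outgroup annotation (e.g. a BRAKER
#' re-annotation) are demoted; the rest are confirmed.  The passing rule
#' is: e-value at or below `max_evalue`, identity strictly above
#' `min_identity`, and both coverages at or above `min_qcov` / `min_scov`.
#'
#' @param candidate_ogs character vector of candidate orthogroup IDs.
#' @param outgroup_hits a `hit_table` of candidate member proteins vs the
#'   alternative annotation.
#' @param query_map named character vector: query gene ID -> orthogroup.
#' @param max_evalue,min_identity,min_qcov,min_scov thresholds (defaults
#'   1e-5, 25, 60, 60).
#' @return list with `confirmed` and `demoted` character vectors
#'   (disjoint; union = `candidate_ogs`), plus `demoting_hits` (the
#'   passing records).
#' @export
rescue_against_alternative_annotation <- function(candidate_ogs,
                                                  outgroup_hits, query_map,
                                                  max_evalue = 1e-5,
                                                  min_identity = 25,
                                                  min_qcov = 60,
                                                  min_scov = 60) {
  pass <- filter_hits(outgroup_hits, max_evalue = max_evalue,
                      min_identity = min_identity, min_qcov = min_qcov,
                      min_scov = min_scov, identity_strict = TRUE)
  og_of <- unname(query_map[pass$query_id])
  demoted <- sort(intersect(candidate_ogs, og_of[!is.na(og_of)]))
  list(confirmed = sort(setdiff(candidate_ogs, demoted)),
       demoted = demoted,
       demoting_hits = pass[!is.na(og_of) & og_of %in% demoted, ,
                            drop = FALSE])
}
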