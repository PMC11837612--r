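ORIGIN_LABELS <- c("duplication_divergence", "hgt", "de_novo_candidate")

#' Filter homology hits on e-value, identity and coverage
#'
#' The screening rule for removing partial or spurious homology: keep a
#' record iff `evalue <= max_evalue`, identity passes `min_identity`, and
#' both coverages are at or above their thresholds.  Two operator regimes
#' are in use in this pipeline and are kept deliberately distinct:
#' the outgroup-screen rule treats identity strictly (`> 25`,
#' `identity_strict = TRUE`, the default), while orthogroup linking uses
#' "equal to or above" (`>= 25`, see [link_orthogroups()]).  Coverage is
#' always `>=` and e-value always `<=`.
#'
#' @param hits a `hit_table` (see [read_hits()]).
#' @param max_evalue maximum e-value (default 1e-5).
#' @param min_identity identity threshold in percent (default 25).
#' @param min_qcov,min_scov minimum query/subject coverage in percent
#'   (default 60).
#' @param identity_strict if `TRUE` identity must be strictly above
#'   `min_identity`; if `FALSE`, at or above.
#' @return the passing subset of `hits`.
#' @export
filter_hits <- function(hits, max_evalue = 1e-5, min_identity = 25,
                        min_qcov = 60, min_scov = 60,
                        identity_strict = TRUE) {
  if (max_evalue < 0) stop("max_evalue must be >= 0")
  if (min_identity < 0 || min_identity > 100 ||
      min_qcov < 0 || min_qcov > 100 || min_scov < 0 || min_scov > 100)
    stop("identity/coverage thresholds must lie in [0, 100]")
  id_ok <- if (identity_strict) hits$pident > min_identity
           else hits$pident >= min_identity
  keep <- hits$evalue <= max_evalue & id_ok &
    hits$qcov >= min_qcov & hits$scov >= min_scov
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify each orthogroup's likely mode of origin
#'
#' Decision table, evaluated in this precedence order for each orthogroup:
#' \enumerate{
#'   \item at least one passing hit against other metazoans, OR (if
#'     `domain_as_duplication`) at least one known protein domain in any
#'     member gene -> `duplication_divergence`;
#'   \item otherwise, at least one passing hit against non-metazoans ->
#'     `hgt`;
#'   \item otherwise -> `de_novo_candidate`.
#' }
#' Metazoan evidence vetoes the HGT call: presence in non-metazoan
#' proteomes only counts as transfer evidence when the family is absent
#' from animals outside the focal clade.  Hit counting is any-member: a
#' hit from any member gene of the orthogroup counts for the whole group.
#'
#' Hits must already be filtered ([filter_hits()]) and must exclude the
#' focal clade itself; a record labelled `focal_clade` in either input is
#' a leakage error.  Hits with query coverage below `partial_qcov` are
#' counted but annotated as partial in the evidence columns (low-coverage
#' matches are the classic signature of spurious homology).
#'
#' @param orthogroups character vector of orthogroup IDs to classify.
#' @param query_map named character vector: member gene ID -> orthogroup.
#' @param domains data.frame from [read_domains()] (already e-value
#'   thresholded), or `NULL` for none.
#' @param metazoan_hits,nonmetazoan_hits filtered `hit_table`s against
#'   metazoan (excluding the focal clade) and non-metazoan sequences.
#' @param domain_as_duplication should a domain alone (no sequence hit)
#'   suffice for the duplication label?  Default `TRUE`.
#' @param partial_qcov query-coverage percentage below which a counted hit
#'   is annotated partial (default 45).
#' @return data.frame of class `origin_calls`: `orthogroup`, `label`,
#'   `n_metazoan_hits`, `n_nonmetazoan_hits`, `n_partial_hits`,
#'   `n_domains`, `domain_accessions`.
#' @export
classify_origin <- function(orthogroups, query_map, domains,
                            metazoan_hits, nonmetazoan_hits,
                            domain_as_duplication = TRUE,
                            partial_qcov = 45) {
  for (h in list(metazoan_hits, nonmetazoan_hits)) {
    if (!is.null(h) && nrow(h) > 0L && any(h$taxon_class == "focal_clade"))
      stop("focal-clade hits present in an 'excluding focal clade' input")
  }
  count_by_og <- function(h) {
    if (is.null(h) || nrow(h) == 0L)
      return(list(n = integer(0), partial = integer(0)))
    og <- unname(query_map[h$query_id])
    keep <- !is.na(og)
    list(n = table(factor(og[keep], levels = orthogroups)),
         partial = table(factor(og[keep & h$qcov < partial_qcov],
                                levels = orthogroups)))
  }
  met <- count_by_og(metazoan_hits)
  non <- count_by_og(nonmetazoan_hits)
  n_met <- if (length(met$n)) as.integer(met$n) else rep(0L, length(orthogroups))
  n_non <- if (length(non$n)) as.integer(non$n) else rep(0L, length(orthogroups))
  n_part <- rep(0L, length(orthogroups))
  if (length(met$partial)) n_part <- n_part + as.integer(met$partial)
  if (length(non$partial)) n_part <- n_part + as.integer(non$partial)

  n_dom <- rep(0L, length(orthogroups))
  dom_acc <- rep("", length(orthogroups))
  if (!is.null(domains) && nrow(domains) > 0L) {
    og <- unname(query_map[domains$gene_id])
    keep <- !is.na(og) & og %in% orthogroups
    if (any(keep)) {
      sp <- split(domains$accession[keep], og[keep])
      idx <- match(names(sp), orthogroups)
      n_dom[idx] <- lengths(sp)
      dom_acc[idx] <- vapply(sp, function(a)
        paste(sort(unique(a)), collapse = ","), character(1))
    }
  }

  dup_evidence <- n_met > 0L | (domain_as_duplication & n_dom > 0L)
  label <- ifelse(dup_evidence, "duplication_divergence",
                  ifelse(n_non > 0L, "hgt", "de_novo_candidate"))
  out <- data.frame(orthogroup = orthogroups, label = label,
                    n_metazoan_hits = n_met, n_nonmetazoan_hits = n_non,
                    n_partial_hits = n_part, n_domains = n_dom,
                    domain_accessions = dom_acc, stringsAsFactors = FALSE)
  class(out) <- c("origin_calls", "data.frame")
  out
}

#' Link homologous orthogroups through reciprocal similarity
#'
#' Starting from a seed orthogroup, finds every orthogroup connected to it
#' through passing member-vs-member hits (identity and both coverages
#' "equal to or above" their thresholds: `>=`, unlike the strict identity
#' rule of the outgroup screen).  Linking is the connected component of
#' the seed in the undirected orthogroup graph whose edges are passing
#' hits.
#'
#' @param seed_og the seed orthogroup ID.
#' @param cross_og_hits a `hit_table` of member proteins vs member
#'   proteins across orthogroups.
#' @param query_map,subject_map named character vectors mapping gene IDs
#'   to orthogroups (often the same map).
#' @param min_identity,min_cov thresholds in percent (defaults 25 and 60),
#'   compared with `>=`.
#' @param max_evalue optional e-value ceiling (default `Inf`: linking is
#'   identity/coverage driven).
#' @return list of class `orthogroup_links`: `seed`, `linked` (sorted IDs,
#'   excluding the seed), `component` (seed + linked) and `linking_hits`.
#' @export
link_orthogroups <- function(seed_og, cross_og_hits, query_map,
                             subject_map = query_map,
                             min_identity = 25, min_cov = 60,
                             max_evalue = Inf) {
  qog <- unname(query_map[cross_og_hits$query_id])
  sog <- unname(subject_map[cross_og_hits$subject_id])
  if (!seed_og %in% c(qog, sog, query_map, subject_map))
    stop("seed orthogroup '", seed_og, "' absent from the hit table maps")
  pass <- cross_og_hits$pident >= min_identity &
    cross_og_hits$qcov >= min_cov & cross_og_hits$scov >= min_cov &
    cross_og_hits$evalue <= max_evalue & !is.na(qog) & !is.na(sog)
  edges <- unique(data.frame(a = qog[pass], b = sog[pass],
                             stringsAsFactors = FALSE))
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  verts <- unique(c(seed_og, edges$a, edges$b))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  comp <- igraph::components(g)
  member <- names(comp$membership)[comp$membership ==
                                     comp$membership[seed_og]]
  structure(list(seed = seed_og,
                 linked = sort(setdiff(member, seed_og)),
                 component = sort(member),
                 linking_hits = cross_og_hits[pass, , drop = FALSE]),
            class = "orthogroup_links")
}

#' Summarise origin-mode counts per gain node
#'
#' @param calls an `origin_calls` data.frame from [classify_origin()].
#' @param gain_map a [assign_gains()] result covering every called
#'   orthogroup.
#' @return data.frame `node` x `label` counts in long form with a `count`
#'   column; per node, the label counts sum to the node's gain count for
#'   the called orthogroups.
#' @export
summarize_modes <- function(calls, gain_map) {
  if (nrow(calls) == 0L)
    return(data.frame(node = character(0), label = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  idx <- match(calls$orthogroup, gain_map$assignments$orthogroup)
  if (anyNA(idx))
    stop("orthogroup(s) with an origin call but no gain assignment: ",
         paste(calls$orthogroup[is.na(idx)], collapse = ", "))
  node <- gain_map$assignments$node[idx]
  tab <- table(node, factor(calls$label, levels = ORIGIN_LABELS))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("node", "label", "count")
  out$count <- as.integer(out$count)
  out[out$count > 0L | TRUE, , drop = FALSE]
}
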