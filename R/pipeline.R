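RUN_CONFIG_KEYS <- c(
  "orthogroups", "tree", "outgroup", "hits_metazoa", "hits_nonmetazoa",
  "domains", "taxon_map", "out_dir", "node",
  "min_species", "max_evalue", "min_identity", "min_qcov", "min_scov",
  "retention_threshold", "alpha", "adjust", "seed")

RUN_CONFIG_NUMERIC <- c("min_species", "max_evalue", "min_identity",
                        "min_qcov", "min_scov", "retention_threshold",
                        "alpha", "seed")

#' Read a flat key = value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment; unknown keys are
#' rejected.  Recognised keys: input paths (`orthogroups`, `tree`,
#' `outgroup`, `hits_metazoa`, `hits_nonmetazoa`, `domains`, `taxon_map`),
#' `out_dir`, the focal `node` (ID or comma-separated focal species
#' list), and thresholds (`min_species`, `max_evalue`, `min_identity`,
#' `min_qcov`, `min_scov`, `retention_threshold`, `alpha`, `adjust`,
#' `seed`).
#'
#' @param path config file path.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad) > 0L) stop("malformed config line: ", lines[bad[1]])
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  unknown <- setdiff(keys, RUN_CONFIG_KEYS)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys)) stop("duplicated config key(s)")
  cfg <- as.list(vals)
  names(cfg) <- keys
  for (k in intersect(keys, RUN_CONFIG_NUMERIC)) cfg[[k]] <- as.numeric(cfg[[k]])
  structure(cfg, class = c("run_config", "list"))
}

default_run_config <- function() {
  list(min_species = 3, max_evalue = 1e-5, min_identity = 25,
       min_qcov = 60, min_scov = 60, retention_threshold = 0.75,
       alpha = 0.05, adjust = "BH", seed = 1)
}

#' Run the full origin-mapping analysis
#'
#' Orchestrates ingest -> gain mapping -> origin classification ->
#' retention and copy-number screening over one configuration, writes the
#' stage outputs (`gain_map.tsv`, `node_counts.tsv`, `origin_calls.tsv`,
#' `mode_summary.tsv`, `copy_matrix.tsv`, `retention.tsv`,
#' `outliers.tsv`, `run_report.tsv`) under `out_dir`, and returns a run
#' report whose stage counts are checked to reconcile: retained +
#' excluded = total orthogroups, per-node gains sum to the retained
#' count, and per-node origin-label counts sum to that node's gain count.
#'
#' @param config a [read_run_config()] result or equivalent named list;
#'   missing thresholds take the package defaults.
#' @return list of class `run_report`: `counts`, `thresholds`, `outputs`,
#'   `version`, plus the in-memory stage results (`gain_map`, `calls`,
#'   `mode_summary`, `retention`, `outliers`).
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(default_run_config(), as.list(config))
  for (k in c("orthogroups", "tree"))
    if (is.null(cfg[[k]])) stop("config is missing required key '", k, "'")

  table <- read_orthogroups(cfg$orthogroups)
  if (length(table$orthogroups) == 0L)
    stop("ingest: orthogroup table is empty")
  phy <- read_newick(cfg$tree, outgroup = cfg$outgroup)

  flt <- filter_min_species(table, min_species = cfg$min_species)
  gm <- assign_gains(phy, flt$retained)

  # focal node: explicit ID, or comma-separated focal species list
  if (!is.null(cfg$node)) {
    if (grepl(",", cfg$node)) {
      focal_species <- trimws(strsplit(cfg$node, ",")[[1L]])
      focal_node <- mrca_node(phy, focal_species)
    } else {
      focal_node <- cfg$node
      focal_species <- setdiff(descendant_leaves(phy, focal_node),
                               character(0))
      focal_species <- intersect(focal_species, leaves(phy))
    }
  } else {
    focal_node <- phy$labels[phy$root]
    focal_species <- leaves(phy)
  }
  node_ogs <- orthogroups_at(gm, focal_node, phy)

  calls <- NULL; msum <- NULL
  if (!is.null(cfg$hits_metazoa) || !is.null(cfg$hits_nonmetazoa) ||
      !is.null(cfg$domains)) {
    tmap <- if (!is.null(cfg$taxon_map)) read_taxon_map(cfg$taxon_map)
            else character(0)
    read_f <- function(p) {
      if (is.null(p)) return(NULL)
      filter_hits(read_hits(p, tmap), max_evalue = cfg$max_evalue,
                  min_identity = cfg$min_identity, min_qcov = cfg$min_qcov,
                  min_scov = cfg$min_scov)
    }
    hm <- read_f(cfg$hits_metazoa)
    hn <- read_f(cfg$hits_nonmetazoa)
    doms <- if (!is.null(cfg$domains)) read_domains(cfg$domains) else NULL
    gene_og <- stats::setNames(
      rep(flt$retained$orthogroups,
          times = vapply(flt$retained$genes, function(x)
            length(unlist(x, use.names = FALSE)), integer(1))),
      unlist(flt$retained$genes, use.names = FALSE))
    calls <- classify_origin(node_ogs, gene_og, doms, hm, hn)
    msum <- summarize_modes(calls, gm)
  }

  cm <- copy_matrix(table, focal_species, orthogroups = node_ogs)
  ret <- retention(cm, threshold = cfg$retention_threshold)
  outl <- if (nrow(cm) >= 2L && stats::sd(as.numeric(cm)) > 0)
    dunn_flag(cm, alpha = cfg$alpha, adjust = cfg$adjust) else NULL

  counts <- list(
    orthogroups_total = length(table$orthogroups),
    orthogroups_retained = length(flt$retained$orthogroups),
    orthogroups_excluded = length(flt$excluded),
    gains_total = nrow(gm$assignments),
    focal_node = focal_node,
    gains_at_focal_node = length(node_ogs),
    retained_75 = sum(ret$retained),
    flagged = if (is.null(outl)) 0L else length(outl$flagged))

  # reconciliation invariants
  stopifnot(counts$orthogroups_retained + counts$orthogroups_excluded ==
              counts$orthogroups_total)
  stopifnot(sum(gm$node_counts) == counts$gains_total)
  if (!is.null(msum)) {
    per_node <- tapply(msum$count, msum$node, sum)
    obs <- gm$node_counts[names(per_node)]
    if (!all(per_node == obs))
      stop("invariant violation: per-node label counts do not sum to gains")
  }

  outputs <- character(0)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f, rn = FALSE) {
      p <- file.path(cfg$out_dir, f)
      utils::write.table(x, p, sep = "\t", quote = FALSE,
                         row.names = rn, col.names = TRUE)
      p
    }
    outputs <- c(
      wt(gm$assignments, "gain_map.tsv"),
      wt(data.frame(node = names(gm$node_counts),
                    gains = unname(gm$node_counts)), "node_counts.tsv"),
      wt(cm, "copy_matrix.tsv", rn = TRUE),
      wt(ret, "retention.tsv"))
    if (!is.null(calls)) outputs <- c(outputs,
      wt(calls, "origin_calls.tsv"), wt(msum, "mode_summary.tsv"))
    if (!is.null(outl)) outputs <- c(outputs, wt(outl$table, "outliers.tsv"))
    thr <- cfg[intersect(names(cfg), RUN_CONFIG_NUMERIC)]
    rep_df <- data.frame(
      key = c(names(counts), names(thr), "version"),
      value = c(vapply(counts, as.character, character(1)),
                vapply(thr, as.character, character(1)),
                as.character(utils::packageVersion("genovmap"))),
      stringsAsFactors = FALSE)
    outputs <- c(outputs, wt(rep_df, "run_report.tsv"))
  }

  structure(list(counts = counts,
                 thresholds = cfg[intersect(names(cfg), RUN_CONFIG_NUMERIC)],
                 outputs = outputs,
                 version = as.character(utils::packageVersion("genovmap")),
                 gain_map = gm, calls = calls, mode_summary = msum,
                 retention = ret, outliers = outl),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:\n")
  for (k in names(x$counts))
    cat("  ", k, ": ", as.character(x$counts[[k]]), "\n", sep = "")
  invisible(x)
}
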