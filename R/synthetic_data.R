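#' Simulation configuration for gene-family evolution
#'
#' Bundles and validates every knob of the synthetic generator.  The
#' defaults mirror the data regime the analysis is designed for: a
#' 115-species tree (99-leaf focal clade plus 16 outgroup species), gains
#' at deep nodes, sporadic loss and occasional duplication producing a
#' right-skewed copy-number distribution with grand mean near 1.16, and
#' origin-mode proportions dominated by duplication-and-divergence with
#' rare horizontal transfer.
#'
#' @param n_orthogroups number of families to simulate (default 500).
#' @param gain_node `"uniform"` (uniform over internal nodes) or a fixed
#'   node ID.
#' @param loss_prob per-branch, per-copy loss probability `q` in `[0, 1)`.
#' @param dup_lambda per-branch, per-surviving-copy expected number of
#'   Poisson duplications (default 0.02).
#' @param mode_props named numeric of planted origin-mode proportions over
#'   `duplication_divergence` / `hgt` / `de_novo_candidate`; must sum to 1.
#' @param domain_prob probability that a duplication family carries a
#'   detectable protein domain (default 0.7).
#' @param hit_noise probability per family of emitting an extra
#'   boundary-straddling hit (identity near 25, coverage near 60); 0 =
#'   noise-free evidence.
#' @param rearrangement_rate expected gene-order rearrangement events per
#'   gene for the synteny generator.
#' @param genes_per_chromosome gene count of each simulated chromosome
#'   (default 41; must be at least 5).
#' @param seed mandatory integer seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_orthogroups = 500L,
                       gain_node = "uniform",
                       loss_prob = 0.1,
                       dup_lambda = 0.02,
                       mode_props = c(duplication_divergence = 0.82,
                                      hgt = 0.01,
                                      de_novo_candidate = 0.17),
                       domain_prob = 0.7,
                       hit_noise = 0,
                       rearrangement_rate = 0.05,
                       genes_per_chromosome = 41L,
                       seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is mandatory")
  if (loss_prob < 0 || loss_prob >= 1)
    stop("loss_prob must lie in [0, 1): q = 1 leaves no surviving family")
  if (dup_lambda < 0) stop("dup_lambda must be >= 0")
  if (!setequal(names(mode_props), ORIGIN_LABELS) ||
      abs(sum(mode_props) - 1) > 1e-8)
    stop("mode_props must cover ", paste(ORIGIN_LABELS, collapse = "/"),
         " and sum to 1")
  if (genes_per_chromosome < 5L)
    stop("need at least 5 genes per simulated chromosome")
  structure(list(n_orthogroups = as.integer(n_orthogroups),
                 gain_node = gain_node, loss_prob = loss_prob,
                 dup_lambda = dup_lambda,
                 mode_props = mode_props[ORIGIN_LABELS],
                 domain_prob = domain_prob, hit_noise = hit_noise,
                 rearrangement_rate = rearrangement_rate,
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Random species tree with a focal clade and outgroups
#'
#' A rooted binary tree whose root splits a focal clade (leaves
#' `lep001...`) from an outgroup clade (`out01...`), the sampling shape of
#' a dense ingroup plus outgroup design.
#'
#' @param n_focal focal-clade leaves (default 99).
#' @param n_outgroup outgroup leaves (default 16).
#' @param seed integer seed.
#' @return list: `phy` (a [as_phylogeny()]), `focal_species`,
#'   `outgroup_species`, `focal_node` (the focal clade's MRCA node ID).
#' @export
sim_species_tree <- function(n_focal = 99L, n_outgroup = 16L, seed) {
  set.seed(seed)
  t1 <- ape::rtree(n_focal, tip.label = sprintf("lep%03d", seq_len(n_focal)))
  t2 <- if (n_outgroup == 1L) NULL
        else ape::rtree(n_outgroup, tip.label = sprintf("out%02d", seq_len(n_outgroup)))
  nw1 <- sub(";$", "", ape::write.tree(t1))
  nw2 <- if (is.null(t2)) "out01" else sub(";$", "", ape::write.tree(t2))
  tree <- ape::read.tree(text = paste0("(", nw1, ",", nw2, ");"))
  phy <- as_phylogeny(tree)
  focal <- sprintf("lep%03d", seq_len(n_focal))
  list(phy = phy, focal_species = focal,
       outgroup_species = setdiff(leaves(phy), focal),
       focal_node = mrca_node(phy, focal))
}

# branch transition: each of n copies survives with prob 1-q; each
# survivor spawns Poisson(lambda) duplicates
branch_copies <- function(n, q, lambda) {
  if (n == 0L) return(c(copies = 0L, losses = 0L))
  surv <- stats::rbinom(1L, n, 1 - q)
  dups <- if (surv > 0L && lambda > 0) stats::rpois(1L, lambda * surv) else 0L
  c(copies = surv + dups, losses = n - surv)
}

#' Simulate gene families by gain, loss and duplication on a tree
#'
#' Each family is born as a single copy at a sampled gain node; along each
#' branch below it, every extant copy is lost with probability `q` and
#' each surviving copy gains `Poisson(lambda)` duplicates.  Leaf copy
#' counts become gene-ID lists (`<species>_<og>_g<k>`), and the true gain
#' node, per-branch loss events and per-species copy counts are returned
#' as ground truth.  Planted origin-mode labels are drawn from
#' `config$mode_props` (deterministic proportions: largest-remainder
#' allocation, then a seeded shuffle).
#'
#' @param phy a [as_phylogeny()].
#' @param config a [sim_config()].
#' @return list: `table` (an [orthogroup_table()]), `truth` (data.frame
#'   `orthogroup`, `gain_node`, `mode`, `n_losses`, `n_species`),
#'   `truth_counts` (integer matrix orthogroup x species).
#' @export
simulate_families <- function(phy, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_og <- config$n_orthogroups
  og_ids <- sprintf("OG%04d", seq_len(n_og))
  internals <- internal_nodes(phy)
  gain_nodes <- if (identical(config$gain_node, "uniform"))
    sample(internals, n_og, replace = TRUE)
  else rep(node_ok(phy, config$gain_node), n_og)

  # planted modes: exact proportions, order shuffled
  n_mode <- floor(config$mode_props * n_og)
  rem <- n_og - sum(n_mode)
  if (rem > 0L) {
    extra <- order(config$mode_props * n_og - n_mode, decreasing = TRUE)
    n_mode[extra[seq_len(rem)]] <- n_mode[extra[seq_len(rem)]] + 1L
  }
  modes <- sample(rep(ORIGIN_LABELS, times = n_mode))

  sp <- leaves(phy)
  counts <- matrix(0L, n_og, length(sp), dimnames = list(og_ids, sp))
  n_losses <- integer(n_og)
  q <- config$loss_prob; lambda <- config$dup_lambda
  for (i in seq_len(n_og)) {
    gn <- node_number(phy, gain_nodes[i])
    copies <- integer(phy$n_node)
    copies[gn] <- 1L
    stack <- gn
    loss_i <- 0L
    while (length(stack) > 0L) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (ch in phy$children[[nd]]) {
        bc <- branch_copies(copies[nd], q, lambda)
        copies[ch] <- bc[["copies"]]
        loss_i <- loss_i + bc[["losses"]]
        if (copies[ch] > 0L) stack <- c(stack, ch)
      }
    }
    counts[i, ] <- copies[seq_len(phy$n_tip)]
    n_losses[i] <- loss_i
  }

  genes <- lapply(seq_len(n_og), function(i) {
    gl <- lapply(seq_along(sp), function(j) {
      k <- counts[i, j]
      if (k == 0L) character(0)
      else paste0(sp[j], "_", og_ids[i], "_g", seq_len(k))
    })
    names(gl) <- sp
    gl
  })
  names(genes) <- og_ids
  truth <- data.frame(orthogroup = og_ids, gain_node = gain_nodes,
                      mode = modes, n_losses = n_losses,
                      n_species = as.integer(rowSums(counts > 0L)),
                      stringsAsFactors = FALSE)
  list(table = orthogroup_table(genes, sp), truth = truth,
       truth_counts = counts)
}

node_ok <- function(phy, node_id) { node_number(phy, node_id); node_id }

#' Simulate taxon-partitioned homology evidence for planted origin modes
#'
#' Emits hit tables, a taxon map and domain annotations whose
#' class-conditional structure matches the planted labels:
#' duplication-and-divergence families get passing metazoan hits and
#' (with probability `domain_prob`) a protein domain; HGT families get
#' passing non-metazoan hits only; de novo candidates get nothing.  With
#' `hit_noise > 0`, families may additionally emit boundary-straddling
#' records (identity near the 25% threshold, coverage near 60%) that
#' exercise the filter's operator semantics.
#'
#' @param sim a [simulate_families()] result.
#' @param config the same [sim_config()].
#' @return list: `hits_metazoa`, `hits_nonmetazoa` (hit tables),
#'   `taxon_map` (named character), `domains` (data.frame), `query_map`
#'   (gene -> orthogroup).
#' @export
simulate_hits <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  truth <- sim$truth
  first_gene <- unname(vapply(truth$orthogroup, function(og) {
    g <- unlist(sim$table$genes[[og]], use.names = FALSE)
    if (length(g) == 0L) paste0("ghost_", og) else g[1L]
  }, character(1)))
  query_map <- stats::setNames(truth$orthogroup, first_gene)
  # full member map for downstream use
  all_genes <- unlist(lapply(truth$orthogroup, function(og)
    unlist(sim$table$genes[[og]], use.names = FALSE)), use.names = FALSE)
  gene_og <- stats::setNames(
    rep(truth$orthogroup,
        times = vapply(truth$orthogroup, function(og)
          length(unlist(sim$table$genes[[og]], use.names = FALSE)),
          integer(1))),
    all_genes)

  mk_hits <- function(idx, class, prefix) {
    if (length(idx) == 0L)
      return(data.frame(query_id = character(0), subject_id = character(0),
                        pident = numeric(0), evalue = numeric(0),
                        qcov = numeric(0), scov = numeric(0),
                        taxon_class = character(0),
                        stringsAsFactors = FALSE))
    n_hits <- 1L + stats::rpois(length(idx), 1.5)
    do.call(rbind, lapply(seq_along(idx), function(m) {
      i <- idx[m]; k <- n_hits[m]
      data.frame(query_id = first_gene[i],
                 subject_id = paste0(prefix, i, "_", seq_len(k)),
                 pident = stats::runif(k, 35, 85),
                 evalue = 10^stats::runif(k, -50, -10),
                 qcov = stats::runif(k, 70, 100),
                 scov = stats::runif(k, 70, 100),
                 taxon_class = class, stringsAsFactors = FALSE)
    }))
  }
  dup_i <- which(truth$mode == "duplication_divergence")
  hgt_i <- which(truth$mode == "hgt")
  hm <- mk_hits(dup_i, "other_metazoa", "met_s")
  hn <- mk_hits(hgt_i, "non_metazoa", "bac_s")

  if (config$hit_noise > 0) {
    noisy <- which(stats::runif(nrow(truth)) < config$hit_noise)
    if (length(noisy) > 0L) {
      extra <- data.frame(
        query_id = first_gene[noisy],
        subject_id = paste0("noise_s", noisy),
        pident = stats::runif(length(noisy), 20, 30),
        evalue = 10^stats::runif(length(noisy), -8, -3),
        qcov = stats::runif(length(noisy), 55, 65),
        scov = stats::runif(length(noisy), 55, 65),
        taxon_class = "other_metazoa", stringsAsFactors = FALSE)
      hm <- rbind(hm, extra)
    }
  }
  # duplication families carry a domain with prob domain_prob
  with_dom <- dup_i[stats::runif(length(dup_i)) < config$domain_prob]
  domains <- data.frame(
    gene_id = first_gene[with_dom],
    accession = sprintf("PF%05d", 1000L + with_dom),
    evalue = 10^stats::runif(length(with_dom), -20, -4),
    stringsAsFactors = FALSE)
  taxon_map <- stats::setNames(c(hm$taxon_class, hn$taxon_class),
                               c(hm$subject_id, hn$subject_id))
  taxon_map <- taxon_map[!duplicated(names(taxon_map))]
  # placeholder queries of extinct families still resolve to their family
  qmap <- c(gene_og, query_map[!names(query_map) %in% names(gene_og)])
  list(hits_metazoa = new_hit_table(hm), hits_nonmetazoa = new_hit_table(hn),
       taxon_map = taxon_map, domains = domains,
       query_map = qmap)
}

#' Simulate gene orders with conserved marker neighbourhoods
#'
#' Each species receives the same ancestral chromosome layout — a target
#' gene embedded between two upstream and two downstream orthologous
#' marker genes, padded with filler genes — and then a
#' `Poisson(rate * n_genes)` number of random position swaps.  At rate 0
#' every pairwise comparison is perfectly conserved; increasing the rate
#' degrades shared-marker counts.
#'
#' @param species character vector of species names.
#' @param config a [sim_config()] (uses `rearrangement_rate`,
#'   `genes_per_chromosome`, `seed`).
#' @param rate optional override of `config$rearrangement_rate`.
#' @return list: `models` (gene-model data.frame across species),
#'   `homology` (gene -> homology group), `targets` (named character,
#'   species -> target gene ID).
#' @export
simulate_gene_orders <- function(species, config, rate = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(rate)) rate <- config$rearrangement_rate
  set.seed(config$seed + 2L)
  n <- config$genes_per_chromosome
  mid <- (n + 1L) %/% 2L
  groups <- sprintf("FAM%03d", seq_len(n))
  groups[mid] <- "TARGET"
  models <- list(); homology <- character(0); targets <- character(0)
  for (sp in species) {
    ids <- paste0(sp, "_", groups)
    ord <- seq_len(n)
    n_events <- stats::rpois(1L, rate * n)
    if (n_events > 0L) {
      for (e in seq_len(n_events)) {
        ij <- sample(n, 2L)
        ord[ij] <- ord[rev(ij)]
      }
    }
    ids_ord <- ids[order(ord)]
    start <- (seq_len(n) - 1L) * 1000L + 1L
    models[[sp]] <- data.frame(
      species = sp, gene_id = ids_ord, chromosome = "chr1",
      start = start, end = start + 500L,
      strand = rep(c("+", "-"), length.out = n),
      n_exons = 2L, n_introns = 1L, stringsAsFactors = FALSE)
    homology <- c(homology, stats::setNames(groups, ids))
    targets[sp] <- paste0(sp, "_TARGET")
  }
  list(models = do.call(rbind, c(models, list(make.row.names = FALSE))),
       homology = homology, targets = targets)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Emits `Orthogroups.tsv`, `tree.nwk`, `hits_metazoa.tsv`,
#' `hits_nonmetazoa.tsv`, `taxon_map.tsv`, `domains.tsv`, `truth.tsv` and
#' per-species `*.gff3` (when gene orders are given).  Identical seeds
#' give byte-identical files.
#'
#' @param sim a [simulate_families()] result.
#' @param phy the phylogeny used.
#' @param dir output directory (created if needed).
#' @param evidence optional [simulate_hits()] result.
#' @param orders optional [simulate_gene_orders()] result.
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, phy, dir, evidence = NULL,
                              orders = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_orthogroups(sim$table, file.path(dir, "Orthogroups.tsv"))
  ape::write.tree(phy$tree, file.path(dir, "tree.nwk"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(evidence)) {
    wh <- function(h, f) {
      out <- h[c("query_id", "subject_id", "pident", "evalue", "qcov", "scov")]
      names(out) <- c("qseqid", "sseqid", "pident", "evalue", "qcovs", "scovs")
      utils::write.table(out, file.path(dir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    wh(evidence$hits_metazoa, "hits_metazoa.tsv")
    wh(evidence$hits_nonmetazoa, "hits_nonmetazoa.tsv")
    utils::write.table(
      data.frame(subject = names(evidence$taxon_map),
                 class = unname(evidence$taxon_map)),
      file.path(dir, "taxon_map.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    utils::write.table(evidence$domains, file.path(dir, "domains.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  if (!is.null(orders)) {
    for (sp in unique(orders$models$species)) {
      d <- orders$models[orders$models$species == sp, , drop = FALSE]
      gff <- c("##gff-version 3",
               unlist(lapply(seq_len(nrow(d)), function(i) {
                 g <- d[i, ]
                 c(paste(g$chromosome, "sim", "gene", g$start, g$end, ".",
                         g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"),
                   paste(g$chromosome, "sim", "mRNA", g$start, g$end, ".",
                         g$strand, ".",
                         paste0("ID=", g$gene_id, ".t1;Parent=", g$gene_id),
                         sep = "\t"),
                   paste(g$chromosome, "sim", "exon", g$start,
                         g$start + 200L, ".", g$strand, ".",
                         paste0("Parent=", g$gene_id, ".t1"), sep = "\t"),
                   paste(g$chromosome, "sim", "exon", g$end - 200L, g$end,
                         ".", g$strand, ".",
                         paste0("Parent=", g$gene_id, ".t1"), sep = "\t"))
               })))
      writeLines(gff, file.path(dir, paste0(sp, ".gff3")))
    }
  }
  invisible(dir)
}
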