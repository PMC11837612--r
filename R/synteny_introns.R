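#' Flanking marker-gene context of a target gene
#'
#' The `n_flank` nearest genes on each side of the target (by start
#' coordinate, strand-agnostic) on the target's chromosome, the raw
#' material for microsynteny comparison.
#'
#' @param gene_models data.frame of gene models (see [read_gff()]).
#' @param target_gene gene ID present in `gene_models`.
#' @param n_flank flank size per side (default 2).
#' @return list of class `marker_context`: `target`, `species`,
#'   `chromosome`, `upstream` (left of target, increasing coordinate),
#'   `downstream`, `order` (all gene IDs on the chromosome in coordinate
#'   order), `position` (target's rank in `order`), `truncated` (fewer
#'   than `n_flank` genes available on at least one side).
#' @export
marker_context <- function(gene_models, target_gene, n_flank = 2L) {
  row <- gene_models[gene_models$gene_id == target_gene, , drop = FALSE]
  if (nrow(row) == 0L) stop("target gene '", target_gene, "' not in models")
  if (nrow(row) > 1L) stop("target gene '", target_gene, "' is ambiguous")
  chr_genes <- gene_models[gene_models$species %in% row$species &
                             gene_models$chromosome == row$chromosome, ,
                           drop = FALSE]
  chr_genes <- chr_genes[order(chr_genes$start), , drop = FALSE]
  ord <- chr_genes$gene_id
  pos <- match(target_gene, ord)
  up <- ord[seq_len(pos - 1L)]
  up <- utils::tail(up, n_flank)
  down <- ord[-seq_len(pos)]
  down <- utils::head(down, n_flank)
  truncated <- length(up) < n_flank || length(down) < n_flank
  if (length(up) + length(down) == 0L)
    warning("target '", target_gene, "' has no neighbours on ",
            row$chromosome)
  structure(list(target = target_gene, species = row$species,
                 chromosome = row$chromosome, upstream = up,
                 downstream = down, order = ord, position = pos,
                 truncated = truncated),
            class = "marker_context")
}

#' Compare two marker contexts for microsynteny conservation
#'
#' A marker of one context is shared when a homologue (same homology
#' group) lies within `window` gene positions of the other context's
#' target on its chromosome.  The shared count is the minimum of the two
#' directional counts, making the comparison symmetric; the verdict is
#' conserved when the shared count reaches `min_shared`.
#'
#' @param ctx_a,ctx_b [marker_context()]s from two different species.
#' @param homology named character vector: gene ID -> homology group
#'   (typically the orthogroup; genes in the same group are homologous).
#' @param window positional window around the target (default 10 genes).
#' @param min_shared markers required for a conserved verdict (default 2).
#' @return list of class `synteny_comparison`: `species`, `targets`,
#'   `shared` (0 to 2 * flank), `max_shared`, `conserved`, `shared_ab`,
#'   `shared_ba`.
#' @export
compare_synteny <- function(ctx_a, ctx_b, homology, window = 10L,
                            min_shared = 2L) {
  if (identical(ctx_a$species, ctx_b$species))
    stop("both contexts are from species '", ctx_a$species, "'")
  near_groups <- function(ctx) {
    lo <- max(1L, ctx$position - window)
    hi <- min(length(ctx$order), ctx$position + window)
    ids <- setdiff(ctx$order[lo:hi], ctx$target)
    unique(stats::na.omit(unname(homology[ids])))
  }
  directional <- function(from, to) {
    markers <- c(from$upstream, from$downstream)
    grp <- unname(homology[markers])
    sum(!is.na(grp) & grp %in% near_groups(to))
  }
  ab <- directional(ctx_a, ctx_b)
  ba <- directional(ctx_b, ctx_a)
  shared <- min(ab, ba)
  structure(list(species = c(ctx_a$species, ctx_b$species),
                 targets = c(ctx_a$target, ctx_b$target),
                 shared = shared,
                 max_shared = min(length(ctx_a$upstream) + length(ctx_a$downstream),
                                  length(ctx_b$upstream) + length(ctx_b$downstream)),
                 conserved = shared >= min_shared,
                 shared_ab = ab, shared_ba = ba),
            class = "synteny_comparison")
}

#' Intron counts for a gene family
#'
#' Per-gene intron counts (exon count of the longest transcript minus
#' one) and the per-subfamily median.  Members missing from the models
#' are listed, not fatal.
#'
#' @param gene_models data.frame of gene models (see [read_gff()]).
#' @param family_members character vector of member gene IDs, or a named
#'   character vector `gene -> subfamily label`.
#' @return list: `per_gene` (data.frame `gene_id`, `subfamily`,
#'   `n_introns`), `per_subfamily` (data.frame `subfamily`, `median_introns`,
#'   `n_genes`), `median_introns` (overall), `missing`.
#' @export
intron_summary <- function(gene_models, family_members) {
  subfam <- names(family_members)
  genes <- unname(family_members)
  if (is.null(subfam)) subfam <- rep("all", length(genes))
  idx <- match(genes, gene_models$gene_id)
  missing <- genes[is.na(idx)]
  keep <- !is.na(idx)
  per_gene <- data.frame(gene_id = genes[keep], subfamily = subfam[keep],
                         n_introns = gene_models$n_introns[idx[keep]],
                         stringsAsFactors = FALSE)
  per_sub <- do.call(rbind, lapply(split(per_gene, per_gene$subfamily),
                                   function(d) data.frame(
                                     subfamily = d$subfamily[1],
                                     median_introns = stats::median(d$n_introns),
                                     n_genes = nrow(d),
                                     stringsAsFactors = FALSE)))
  rownames(per_sub) <- NULL
  list(per_gene = per_gene, per_subfamily = per_sub,
       median_introns = stats::median(per_gene$n_introns),
       missing = missing)
}
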