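#' Orthogroup membership table
#'
#' Container for an OrthoFinder-style orthogroup table: one orthogroup per
#' row, one species per column, each cell a (possibly empty) list of gene
#' IDs.  Copy counts are materialised once into an integer matrix because
#' every downstream module (gain mapping, retention, copy-number tests)
#' works from counts.
#'
#' @param genes a named list: orthogroup ID -> named list (species ->
#'   character vector of gene IDs).  Every inner list must be named with
#'   species from `species`.
#' @param species the species roster, in column order.
#' @return an object of class `orthogroup_table` with elements `genes`,
#'   `species`, `orthogroups` and `counts` (integer matrix, orthogroup x
#'   species).
#' @export
orthogroup_table <- function(genes, species) {
  if (anyDuplicated(species)) stop("species roster contains duplicates")
  og_ids <- names(genes)
  if (length(genes) == 0L) og_ids <- character(0)
  if (is.null(og_ids) || anyDuplicated(og_ids))
    stop("orthogroup IDs must be unique and named")
  counts <- matrix(0L, nrow = length(genes), ncol = length(species),
                   dimnames = list(og_ids, species))
  for (og in og_ids) {
    sp_in <- names(genes[[og]])
    bad <- setdiff(sp_in, species)
    if (length(bad) > 0L)
      stop("orthogroup ", og, " has species outside the roster: ",
           paste(bad, collapse = ", "))
    counts[og, sp_in] <- vapply(genes[[og]], length, integer(1))
  }
  # gene IDs must be unique within each species column
  for (sp in species) {
    g <- unlist(lapply(genes, function(x) x[[sp]]), use.names = FALSE)
    if (anyDuplicated(g))
      stop("duplicated gene IDs within species ", sp, ": ",
           paste(unique(g[duplicated(g)]), collapse = ", "))
  }
  structure(list(genes = genes, species = species,
                 orthogroups = og_ids, counts = counts),
            class = "orthogroup_table")
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat("orthogroup_table: ", length(x$orthogroups), " orthogroups x ",
      length(x$species), " species, ", sum(x$counts), " genes\n", sep = "")
  invisible(x)
}

#' Read an Orthogroups.tsv file
#'
#' Parses the OrthoFinder `Orthogroups.tsv` dialect: a header line
#' `Orthogroup<TAB>sp1<TAB>...`, then one row per orthogroup whose cells
#' are `", "`-separated gene ID lists (empty cell = species absent).
#'
#' @param path path to the TSV file.
#' @return an [orthogroup_table()].
#' @export
read_orthogroups <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) stop("empty orthogroup file: ", path)
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  if (length(header) < 2L)
    stop("orthogroup header must have at least one species column")
  species <- header[-1L]
  ncol_exp <- length(header)
  genes <- vector("list", length(cells) - 1L)
  og_ids <- character(length(genes))
  for (i in seq_along(genes)) {
    row <- cells[[i + 1L]]
    # trailing empty cells are dropped by strsplit; pad them back
    if (length(row) < ncol_exp) row <- c(row, rep("", ncol_exp - length(row)))
    if (length(row) != ncol_exp)
      stop("ragged row at line ", i + 1L, ": expected ", ncol_exp,
           " columns, found ", length(row))
    og_ids[i] <- row[1L]
    gl <- lapply(row[-1L], function(cell) {
      if (!nzchar(trimws(cell))) return(character(0))
      ids <- trimws(strsplit(cell, ",", fixed = TRUE)[[1L]])
      ids[nzchar(ids)]
    })
    names(gl) <- species
    genes[[i]] <- gl
  }
  if (anyDuplicated(og_ids))
    stop("duplicated orthogroup ID(s): ",
         paste(unique(og_ids[duplicated(og_ids)]), collapse = ", "))
  names(genes) <- og_ids
  orthogroup_table(genes, species)
}

#' Write an orthogroup table back to Orthogroups.tsv format
#' @param table an [orthogroup_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(table, path) {
  header <- paste(c("Orthogroup", table$species), collapse = "\t")
  rows <- vapply(table$orthogroups, function(og) {
    cells <- vapply(table$species, function(sp) {
      paste(table$genes[[og]][[sp]], collapse = ", ")
    }, character(1))
    paste(c(og, cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Presence sets of an orthogroup table
#' @param table an [orthogroup_table()].
#' @return named list: orthogroup -> character vector of species with at
#'   least one copy.
#' @export
presence_sets <- function(table) {
  lapply(stats::setNames(table$orthogroups, table$orthogroups),
         function(og) table$species[table$counts[og, ] > 0L])
}

VALID_TAXON_CLASSES <- c("focal_clade", "other_metazoa", "non_metazoa")

#' Read a subject-to-taxon-class map
#'
#' Two-column TSV (`subject_id`, `class`), with classes in
#' `focal_clade` / `other_metazoa` / `non_metazoa`.  Taxonomy is always
#' supplied explicitly; it is never guessed from subject IDs.
#'
#' @param path path to the TSV (with or without a header line).
#' @return named character vector: subject ID -> class.
#' @export
read_taxon_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("taxon map must have two columns")
  if (tolower(df[1, 1]) %in% c("subject", "subject_id")) df <- df[-1, , drop = FALSE]
  cls <- df[[2L]]
  bad <- setdiff(unique(cls), VALID_TAXON_CLASSES)
  if (length(bad) > 0L)
    stop("unknown taxon class(es): ", paste(bad, collapse = ", "),
         " (expected ", paste(VALID_TAXON_CLASSES, collapse = "/"), ")")
  stats::setNames(cls, df[[1L]])
}

new_hit_table <- function(df) {
  need <- c("query_id", "subject_id", "pident", "evalue",
            "qcov", "scov", "taxon_class")
  stopifnot(all(need %in% names(df)))
  rngbad <- with(df, pident < 0 | pident > 100 | qcov < 0 | qcov > 100 |
                   scov < 0 | scov > 100 | evalue < 0)
  if (any(rngbad, na.rm = TRUE))
    stop("hit record(s) out of range (identity/coverage in [0,100], evalue >= 0)")
  if (anyNA(df[need[1:6]])) stop("hit table contains missing values")
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Read tabular homology hits (BLAST outfmt-6 dialect)
#'
#' Accepts either the 12-column tab-separated outfmt 6
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`), the 14-column extension with `qlen slen` appended,
#' or a headered TSV carrying `qcovs`/`scovs` directly.  When coverage
#' columns are absent it is computed from alignment coordinates as
#' `(end - start + 1) / length * 100` (1-based inclusive spans).
#'
#' @param path path to the hit TSV.
#' @param taxon_map named character vector (subject -> class), e.g. from
#'   [read_taxon_map()].
#' @param on_missing_subject what to do when a subject is absent from
#'   `taxon_map`: `"error"` (default) or `"drop"` (drop with a warning;
#'   the number dropped is reported in attribute `n_dropped`).
#' @return a `hit_table` data.frame with columns `query_id`, `subject_id`,
#'   `pident`, `evalue`, `qcov`, `scov`, `taxon_class`.
#' @export
read_hits <- function(path, taxon_map,
                      on_missing_subject = c("error", "drop")) {
  on_missing_subject <- match.arg(on_missing_subject)
  dt <- data.table::fread(path, sep = "\t", header = "auto",
                          colClasses = NULL, data.table = FALSE)
  nm <- tolower(names(dt))
  headered <- any(c("qseqid", "query", "query_id") %in% nm)
  if (headered) {
    names(dt) <- nm
    pick <- function(...) {
      for (cand in c(...)) if (cand %in% nm) return(dt[[cand]])
      NULL
    }
    query <- pick("qseqid", "query", "query_id")
    subject <- pick("sseqid", "subject", "subject_id")
    pident <- pick("pident", "percent_identity")
    evalue <- pick("evalue")
    qcov <- pick("qcovs", "qcov", "query_coverage")
    scov <- pick("scovs", "scov", "subject_coverage")
    if (is.null(qcov)) {
      qs <- pick("qstart"); qe <- pick("qend"); ql <- pick("qlen")
      ss <- pick("sstart"); se <- pick("send"); sl <- pick("slen")
      if (is.null(qs) || is.null(ql) || is.null(ss) || is.null(sl))
        stop("hit table needs qcovs/scovs or qstart,qend,qlen,sstart,send,slen")
      qcov <- (abs(qe - qs) + 1) / ql * 100
      scov <- (abs(se - ss) + 1) / sl * 100
    }
  } else {
    if (!ncol(dt) %in% c(12L, 14L))
      stop("headerless hit table must have 12 or 14 columns, found ", ncol(dt))
    query <- dt[[1L]]; subject <- dt[[2L]]; pident <- dt[[3L]]
    evalue <- dt[[11L]]
    if (ncol(dt) == 14L) {
      qcov <- (abs(dt[[8L]] - dt[[7L]]) + 1) / dt[[13L]] * 100
      scov <- (abs(dt[[10L]] - dt[[9L]]) + 1) / dt[[14L]] * 100
    } else {
      stop("12-column outfmt 6 lacks qlen/slen; supply the 14-column ",
           "variant or qcovs/scovs columns")
    }
  }
  for (v in list(pident, evalue, qcov, scov)) {
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("malformed numeric field in hit table at data line ", bad)
    }
  }
  cls <- unname(taxon_map[subject])
  miss <- is.na(cls)
  n_dropped <- 0L
  if (any(miss)) {
    if (on_missing_subject == "error")
      stop(sum(miss), " subject(s) absent from taxon map, e.g. ",
           subject[which(miss)[1]])
    n_dropped <- sum(miss)
    warning("dropped ", n_dropped, " hit(s) with subjects absent from taxon map")
  }
  out <- data.frame(query_id = query, subject_id = subject,
                    pident = as.numeric(pident), evalue = as.numeric(evalue),
                    qcov = as.numeric(qcov), scov = as.numeric(scov),
                    taxon_class = cls, stringsAsFactors = FALSE)[!miss, , drop = FALSE]
  rownames(out) <- NULL
  out <- new_hit_table(out)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read protein-domain annotations
#'
#' TSV with columns `gene_id`, `accession`, `evalue` (header optional).
#' Genes absent from the file simply have no detected domain.
#'
#' @param path path to the TSV.
#' @param max_evalue keep only domain hits with e-value at or below this
#'   threshold (default `1e-3`, the usual Pfam reporting cutoff).
#' @return data.frame with columns `gene_id`, `accession`, `evalue`.
#' @export
read_domains <- function(path, max_evalue = 1e-3) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("domain table must have gene_id, accession, evalue")
  if (is.character(df[[3L]]) || tolower(df[1, 1]) == "gene_id") {
    ev1 <- suppressWarnings(as.numeric(df[1, 3]))
    if (is.na(ev1)) df <- df[-1, , drop = FALSE]
  }
  out <- data.frame(gene_id = as.character(df[[1L]]),
                    accession = as.character(df[[2L]]),
                    evalue = as.numeric(df[[3L]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$evalue) || any(out$evalue < 0))
    stop("domain e-values must be non-negative numbers")
  out[out$evalue <= max_evalue, , drop = FALSE]
}

#' Read gene models from a GFF3 file
#'
#' Extracts per-gene coordinates and per-transcript exon counts from the
#' `gene` / `mRNA` / `exon` features of a GFF3 file.  The per-gene exon
#' count is that of the longest transcript (summed exon length); the
#' intron count is `exon_count - 1`.
#'
#' @param path path to the GFF3 file.
#' @param species species label to attach to every model.
#' @return data.frame with columns `species`, `gene_id`, `chromosome`,
#'   `start`, `end`, `strand`, `n_exons`, `n_introns`.
#' @export
read_gff <- function(path, species = NA_character_) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(f) == 9L
  if (!all(ok)) stop("malformed GFF3 line(s): ", which(!ok)[1])
  m <- do.call(rbind, f)
  type <- m[, 3L]
  attr_field <- m[, 9L]
  get_tag <- function(attrs, tag) {
    pat <- paste0("(^|;)", tag, "=([^;]*)")
    hit <- regmatches(attrs, regexec(pat, attrs))
    vapply(hit, function(h) if (length(h) >= 3L) h[3L] else NA_character_,
           character(1))
  }
  gi <- type == "gene"
  genes <- data.frame(
    gene_id = get_tag(attr_field[gi], "ID"),
    chromosome = m[gi, 1L], start = as.integer(m[gi, 4L]),
    end = as.integer(m[gi, 5L]), strand = m[gi, 7L],
    stringsAsFactors = FALSE)
  if (any(genes$start > genes$end)) stop("gene with start > end in ", path)

  mi <- type %in% c("mRNA", "transcript")
  tx <- data.frame(tx_id = get_tag(attr_field[mi], "ID"),
                   parent = get_tag(attr_field[mi], "Parent"),
                   stringsAsFactors = FALSE)
  ei <- type == "exon"
  ex <- data.frame(parent = get_tag(attr_field[ei], "Parent"),
                   start = as.integer(m[ei, 4L]),
                   end = as.integer(m[ei, 5L]),
                   stringsAsFactors = FALSE)
  # exon Parent may list several transcripts, comma-separated
  ex <- do.call(rbind, lapply(seq_len(nrow(ex)), function(i) {
    ps <- strsplit(ex$parent[i], ",", fixed = TRUE)[[1L]]
    data.frame(parent = ps, start = ex$start[i], end = ex$end[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(ex)) ex <- data.frame(parent = character(0),
                                    start = integer(0), end = integer(0))

  gene_span <- stats::setNames(split(genes[c("start", "end")],
                                     seq_len(nrow(genes))), genes$gene_id)
  tx_gene <- stats::setNames(tx$parent, tx$tx_id)
  n_exons <- integer(nrow(genes)); names(n_exons) <- genes$gene_id
  best_len <- stats::setNames(rep(-1, nrow(genes)), genes$gene_id)
  if (nrow(ex) > 0L) {
    sp <- split(ex, ex$parent)
    for (txid in names(sp)) {
      g <- tx_gene[txid]
      if (is.na(g) || !g %in% genes$gene_id) next
      exons <- sp[[txid]]
      span <- gene_span[[g]]
      if (any(exons$start < span$start | exons$end > span$end))
        warning("exon outside parent gene span for transcript ", txid)
      len <- sum(exons$end - exons$start + 1L)
      if (len > best_len[g]) {
        best_len[g] <- len
        n_exons[g] <- nrow(exons)
      }
    }
  }
  if (any(n_exons == 0L)) n_exons[n_exons == 0L] <- 1L  # gene with no exon rows
  genes$species <- species
  genes$n_exons <- unname(n_exons[genes$gene_id])
  genes$n_introns <- genes$n_exons - 1L
  genes[c("species", "gene_id", "chromosome", "start", "end",
          "strand", "n_exons", "n_introns")]
}

#' Read an expression matrix and average replicates
#'
#' @param path TSV: first column gene IDs, remaining columns samples
#'   (header required).
#' @param meta data.frame with columns `sample`, `tissue`, `lifestage`;
#'   replicate samples of the same (tissue, lifestage) are averaged into
#'   one column named `tissue.lifestage`.
#' @return numeric matrix, genes x (tissue, lifestage) conditions.
#' @export
read_expression <- function(path, meta) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- df[[1L]]
  if (any(mat < 0, na.rm = TRUE)) stop("negative abundance in ", path)
  stopifnot(all(c("sample", "tissue", "lifestage") %in% names(meta)))
  miss <- setdiff(colnames(mat), meta$sample)
  if (length(miss) > 0L)
    stop("samples without metadata: ", paste(miss, collapse = ", "))
  key <- paste(meta$tissue, meta$lifestage, sep = ".")
  names(key) <- meta$sample
  grp <- key[colnames(mat)]
  out <- vapply(unique(grp), function(g) {
    rowMeans(mat[, grp == g, drop = FALSE])
  }, numeric(nrow(mat)))
  if (is.null(dim(out))) out <- matrix(out, ncol = 1,
                                       dimnames = list(rownames(mat),
                                                       unique(grp)))
  out
}
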