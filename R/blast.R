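#' Parse a 12-column tabular similarity-hit file
#'
#' Reads the standard BLASTP tabular dialect (outfmt-6 style): qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore. Comment lines starting with `#` are skipped. In
#' strict mode (default) a malformed line - wrong column count or
#' non-numeric evalue/bitscore - aborts with its line number; otherwise
#' malformed lines are dropped with a warning listing them.
#'
#' @param path hit file path.
#' @param query_proteome,subject_proteome labels recording the search
#'   direction (query -> subject).
#' @param strict abort on malformed lines.
#' @return data frame of class `hit_table` with typed columns and
#'   attributes `query_proteome`, `subject_proteome`.
#' @export
read_blast_tab <- function(path, query_proteome = NA_character_,
                           subject_proteome = NA_character_,
                           strict = TRUE) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!length(lines)) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12), cols),
                         stringsAsFactors = FALSE)
    num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
             "sstart", "send", "evalue", "bitscore")
    out[num] <- lapply(out[num], as.numeric)
    return(.as_hit_table(out, query_proteome, subject_proteome))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 12
  if (!any(bad)) {
    m0 <- matrix(unlist(parts), ncol = 12, byrow = TRUE)
    ev <- suppressWarnings(as.numeric(m0[, 11]))
    bs <- suppressWarnings(as.numeric(m0[, 12]))
    bad <- is.na(ev) | is.na(bs)
  }
  if (any(bad)) {
    msg <- paste0("malformed hit line(s) ",
                  paste(lineno[bad], collapse = ", "), " in ", path)
    if (strict) stop(msg)
    warning(msg, "; dropped")
    parts <- parts[!bad]
    if (!length(parts)) {
      empty <- as.data.frame(setNames(rep(list(character(0)), 12), cols),
                             stringsAsFactors = FALSE)
      return(.as_hit_table(empty, query_proteome, subject_proteome))
    }
  }
  m <- matrix(unlist(parts), ncol = 12, byrow = TRUE)
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2], stringsAsFactors = FALSE)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  if (nrow(m) == 1) num <- matrix(num, nrow = 1)
  colnames(num) <- cols[3:12]
  out <- cbind(out, as.data.frame(num))
  if (any(out$evalue < 0, na.rm = TRUE))
    stop("negative E-value in ", path)
  .as_hit_table(out, query_proteome, subject_proteome)
}

.as_hit_table <- function(df, query_proteome, subject_proteome) {
  attr(df, "query_proteome") <- query_proteome
  attr(df, "subject_proteome") <- subject_proteome
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Best hit per query
#'
#' For each query, the hit with the smallest E-value among hits with
#' `evalue < evalue_max`. Ties are broken deterministically: largest
#' bitscore, then lexicographically smallest subject id. Queries with no
#' passing hit are absent from the result.
#'
#' @param table a [read_blast_tab()] hit table.
#' @param evalue_max exclusive E-value cutoff (default 0.001).
#' @return data frame, one row per query.
#' @export
best_hits <- function(table, evalue_max = 0.001) {
  h <- table[table$evalue < evalue_max, , drop = FALSE]
  if (!nrow(h)) return(h[0, , drop = FALSE])
  o <- order(h$qseqid, h$evalue, -h$bitscore, h$sseqid)
  h <- h[o, , drop = FALSE]
  out <- h[!duplicated(h$qseqid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits between two proteomes
#'
#' Pairs (gene_a, gene_b) where gene_b is gene_a's best hit in the a->b
#' search and gene_a is gene_b's best hit in the b->a search - the
#' operational ortholog call. The reported bitscore is the maximum-score
#' a->b hit line for the pair (a pair with several HSP lines contributes
#' its single best line, not a sum).
#'
#' @param ab hit table, proteome A as query against proteome B.
#' @param ba the reciprocal search.
#' @param evalue_max exclusive E-value cutoff applied to both directions.
#' @return data frame with columns `gene_a`, `gene_b`, `bitscore`.
#' @export
reciprocal_best_hits <- function(ab, ba, evalue_max = 0.001) {
  qa <- attr(ab, "query_proteome"); sa <- attr(ab, "subject_proteome")
  qb <- attr(ba, "query_proteome"); sb <- attr(ba, "subject_proteome")
  if (!is.na(qa) && !is.na(qb) && !(identical(qa, sb) && identical(sa, qb)))
    stop("hit tables are not reciprocal directions of the same proteome pair")
  ba_best <- best_hits(ba, evalue_max)
  ab_best <- best_hits(ab, evalue_max)
  if (!nrow(ab_best) || !nrow(ba_best))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE))
  back <- setNames(ba_best$sseqid, ba_best$qseqid)
  hit <- ab_best[!is.na(back[ab_best$sseqid]) &
                   back[ab_best$sseqid] == ab_best$qseqid, , drop = FALSE]
  if (!nrow(hit))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE))
  # max-scoring a->b line for each reciprocal pair
  key <- paste(ab$qseqid, ab$sseqid, sep = "\r")
  want <- paste(hit$qseqid, hit$sseqid, sep = "\r")
  sc <- vapply(want, function(k) max(ab$bitscore[key == k]), numeric(1))
  out <- data.frame(gene_a = hit$qseqid, gene_b = hit$sseqid,
                    bitscore = unname(sc), stringsAsFactors = FALSE)
  out[order(out$gene_a), , drop = FALSE]
}

#' Lineage-specific genes
#'
#' A focal gene is lineage-specific when no proteome outside the lineage
#' has any hit to it below the E-value threshold (any hit counts, not
#' only reciprocal best ones). Raising `evalue_max` admits more hits and
#' can only shrink the lineage-specific set.
#'
#' @param focal_genes character vector of focal-species gene ids.
#' @param outgroup_tables named list of hit tables (focal proteome as
#'   query), keyed by outgroup species id.
#' @param lineage character vector of in-lineage species ids; must be
#'   disjoint from `names(outgroup_tables)`.
#' @param evalue_max exclusive E-value cutoff (default 0.001).
#' @return character vector (subset of `focal_genes`), input order.
#' @export
find_lineage_specific <- function(focal_genes, outgroup_tables, lineage,
                                  evalue_max = 0.001) {
  stopifnot(is.list(outgroup_tables), !is.null(names(outgroup_tables)))
  overlap <- intersect(names(outgroup_tables), lineage)
  if (length(overlap))
    stop("lineage species also given as outgroups: ",
         paste(overlap, collapse = ", "))
  hit_any <- unique(unlist(lapply(outgroup_tables, function(tab)
    tab$qseqid[tab$evalue < evalue_max])))
  focal_genes[!focal_genes %in% hit_any]
}

#' Assemble per-gene score profiles from ortholog assignments
#'
#' Combines an ortholog map (long format: one row per gene x species
#' assignment with its bitscore), a distance set, and focal self-scores
#' into [score_profile] objects: the \eqn{t = 0} self-score plus one
#' (distance, bitscore) point per assigned ortholog. Genes with fewer
#' than 3 points are kept - the fit flags them `insufficient_data`
#' (eligibility needs at least 3 observed homologs including the focal
#' gene) - never silently dropped.
#'
#' @param orthologs data frame with columns `gene_id`, `species_id`,
#'   `ortholog_id`, `bitscore`.
#' @param distances a [species_distances] object (focal at 0).
#' @param self_scores named numeric vector: focal gene id -> self
#'   bitscore; every gene in `orthologs` (and any extra gene to carry
#'   through) must be present.
#' @return named list of [score_profile] objects, ordered by
#'   `names(self_scores)`.
#' @export
build_score_profiles <- function(orthologs, distances, self_scores) {
  stopifnot(all(c("gene_id", "species_id", "bitscore") %in% names(orthologs)),
            inherits(distances, "species_distances"),
            !is.null(names(self_scores)))
  focal <- attr(distances, "focal_species")
  miss_sp <- setdiff(unique(orthologs$species_id), names(distances))
  if (length(miss_sp))
    stop("ortholog species without a distance: ",
         paste(miss_sp, collapse = ", "))
  miss_g <- setdiff(unique(orthologs$gene_id), names(self_scores))
  if (length(miss_g))
    stop("genes with orthologs but no self-score: ",
         paste(miss_g, collapse = ", "))
  out <- lapply(names(self_scores), function(g) {
    o <- orthologs[orthologs$gene_id == g & orthologs$species_id != focal, ,
                   drop = FALSE]
    score_profile(c(focal, o$species_id),
                  c(0, as.numeric(distances[o$species_id])),
                  c(self_scores[[g]], o$bitscore),
                  gene_id = g, focal_species = focal)
  })
  setNames(out, names(self_scores))
}

#' Sequence lengths of a proteome FASTA
#'
#' Used for the query-length term of [bitscore_threshold()] and for
#' database sizes (sum of lengths).
#'
#' @param path protein FASTA file.
#' @return named integer vector of residue counts (first id token).
#' @export
protein_lengths <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(Biostrings::width(ss), sub("\\s.*$", "", names(ss)))
}
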