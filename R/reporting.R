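# Reporting: per-genome copy-number matrices, operon tables and
# iTOL-ready datasets.

.count_matrix <- function(genomes, genome_col, label_col) {
  labels <- sort(unique(label_col[!is.na(label_col)]))
  m <- matrix(0L, nrow = length(genomes), ncol = length(labels),
              dimnames = list(genomes, labels))
  if (length(label_col)) {
    keep <- !is.na(label_col)
    tab <- table(factor(genome_col[keep], levels = genomes),
                 factor(label_col[keep], levels = labels))
    m[] <- as.integer(tab)
  }
  m
}

#' Per-genome copy-number matrices
#'
#' Builds the four matrices reported per run: occurrences of each hit
#' cluster, partner cluster, operon type and discarded-hit cluster in every
#' input genome. Genomes contributing nothing appear as all-zero rows, so
#' presence/absence across the whole collection is directly comparable.
#' In `both` orientation the partner matrix disambiguates the two
#' independently-clustered networks with `_up`/`_down` column suffixes.
#'
#' @param labeled_operons operon data.frame from [label_operons()].
#' @param discarded discarded-hit data.frame from [filter_operons()].
#' @param discarded_assign assignment from [map_discarded()].
#' @param genomes character vector: the full genome universe of the run.
#' @param orientation orientation requirement used in filtering.
#' @return named list of integer matrices: `hits`, `partners`, `operons`,
#'   `discarded`.
#' @export
tabulate_counts <- function(labeled_operons, discarded, discarded_assign,
                            genomes, orientation = "either") {
  genomes <- unique(as.character(genomes))
  ops <- labeled_operons
  hits_m <- .count_matrix(genomes, ops$genome_id, ops$hit_cluster)
  operons_m <- .count_matrix(genomes, ops$genome_id, ops$operon_type)
  pg <- c(ops$genome_id[!is.na(ops$partner_up_cluster)],
          ops$genome_id[!is.na(ops$partner_down_cluster)])
  up_lab <- ops$partner_up_cluster[!is.na(ops$partner_up_cluster)]
  dn_lab <- ops$partner_down_cluster[!is.na(ops$partner_down_cluster)]
  if (orientation == "both") {
    pl <- c(paste0(up_lab, "_up"), paste0(dn_lab, "_down"))
  } else {
    pl <- c(up_lab, dn_lab)
  }
  partners_m <- .count_matrix(genomes, pg, pl)
  d_lab <- discarded_assign$cluster[match(discarded$hit_orf_id,
                                          discarded_assign$seq_id)]
  discarded_m <- .count_matrix(genomes, discarded$genome_id, d_lab)
  list(hits = hits_m, partners = partners_m, operons = operons_m,
       discarded = discarded_m)
}

#' Export a count matrix as an iTOL heatmap dataset
#'
#' Emits the text block iTOL consumes as a `DATASET_HEATMAP`: a header with
#' separator declaration, dataset label and field labels (the cluster
#' labels), then one data line per genome. Row names must match the leaf
#' names of the tree the dataset will be dropped onto (the tree itself is
#' not generated here). Copy number matters biologically (multi-copy
#' arrays), hence a heatmap rather than binary presence/absence;
#' `binary = TRUE` collapses counts to 0/1 if preferred.
#'
#' @param matrix count matrix (genomes x labels).
#' @param title dataset label shown in iTOL.
#' @param sep separator: `"comma"` (default) or `"tab"`.
#' @param binary export presence/absence instead of counts.
#' @param path optional file to write to.
#' @return character vector of dataset lines (invisibly if `path` given).
#' @export
export_itol <- function(matrix, title, sep = c("comma", "tab"),
                        binary = FALSE, path = NULL) {
  sep <- match.arg(sep)
  sep_chr <- if (sep == "comma") "," else "\t"
  ids <- rownames(matrix)
  if (any(grepl(sep_chr, ids, fixed = TRUE)))
    stop("separator character occurs in a genome id; use the other separator")
  if (grepl(sep_chr, title, fixed = TRUE))
    stop("separator character occurs in the dataset title")
  m <- matrix
  if (binary) m[] <- as.integer(m > 0)
  header <- c(
    "DATASET_HEATMAP",
    paste0("SEPARATOR ", toupper(sep)),
    paste0("DATASET_LABEL", sep_chr, title),
    paste0("COLOR", sep_chr, "#08306b"),
    paste0("FIELD_LABELS", sep_chr,
           paste(colnames(m), collapse = sep_chr)),
    "DATA")
  if (ncol(m) == 0L || nrow(m) == 0L) {
    warning("empty count matrix: emitting header-only iTOL dataset")
    lines <- header
  } else {
    data_lines <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(ids[i], m[i, ]), collapse = sep_chr)
    }, character(1))
    lines <- c(header, data_lines)
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse the data lines of an iTOL heatmap dataset back into a matrix
#'
#' Inverse of [export_itol()] for counts; used to verify the export is
#' lossless.
#'
#' @param lines character vector as produced by [export_itol()].
#' @return integer count matrix.
#' @export
parse_itol <- function(lines) {
  sep_line <- grep("^SEPARATOR ", lines, value = TRUE)[1]
  sep_chr <- if (grepl("TAB", sep_line)) "\t" else ","
  labels <- strsplit(sub("^FIELD_LABELS.", "",
                         grep("^FIELD_LABELS", lines, value = TRUE)[1]),
                     sep_chr, fixed = TRUE)[[1]]
  data_at <- which(lines == "DATA")
  data_lines <- lines[seq_along(lines) > data_at]
  data_lines <- data_lines[nzchar(data_lines)]
  if (!length(data_lines))
    return(matrix(0L, 0, length(labels), dimnames = list(NULL, labels)))
  parts <- strsplit(data_lines, sep_chr, fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  m <- t(vapply(parts, function(p) as.integer(p[-1L]),
                integer(length(labels))))
  dimnames(m) <- list(ids, labels)
  m
}

#' Write the detailed per-operon table
#'
#' One row per accepted operon and per discarded hit: location, hit profile
#' and score, per-side partner coordinates and gaps, cluster labels, status
#' and discard reason, sorted by genome, contig and hit start so output is
#' deterministic under shuffled input.
#'
#' @param labeled_operons operon data.frame from [label_operons()].
#' @param discarded discarded-hit data.frame.
#' @param discarded_assign assignment from [map_discarded()] (may be empty).
#' @param path optional TSV output file.
#' @return the table data.frame (invisibly if `path` given).
#' @export
write_operon_table <- function(labeled_operons, discarded,
                               discarded_assign = NULL, path = NULL) {
  cols <- c("genome_id", "contig_id", "strand", "profile", "bitscore",
            "hit_start", "hit_end",
            "partner_up_start", "partner_up_end", "partner_up_gap_bp",
            "partner_down_start", "partner_down_end", "partner_down_gap_bp",
            "hit_cluster", "partner_up_cluster", "partner_down_cluster",
            "operon_type", "status", "reason")
  ops <- labeled_operons
  if (nrow(ops)) {
    ops$status <- "accepted"; ops$reason <- NA_character_
  } else {
    ops$status <- character(0); ops$reason <- character(0)
  }
  for (c_ in cols) if (!c_ %in% names(ops)) ops[[c_]] <- rep(NA, nrow(ops))
  dis <- discarded
  if (nrow(dis)) {
    dis$status <- "discarded"
    if (!is.null(discarded_assign) && nrow(discarded_assign)) {
      dis$hit_cluster <- discarded_assign$cluster[
        match(dis$hit_orf_id, discarded_assign$seq_id)]
    }
  } else {
    dis$status <- character(0)
  }
  for (c_ in cols) if (!c_ %in% names(dis)) dis[[c_]] <- rep(NA, nrow(dis))
  tab <- rbind(ops[, cols, drop = FALSE], dis[, cols, drop = FALSE])
  tab <- tab[order(tab$genome_id, tab$contig_id, tab$hit_start), ,
             drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    return(invisible(tab))
  }
  tab
}
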