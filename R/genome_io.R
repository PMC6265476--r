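# Genome input and ORF extraction.
#
# A genome is a named list of contig sequences; candidate coding sequences
# come from six-frame translation with prokaryotic start-codon priority
# (ATG, then TTG, then GTG within each stop-to-stop segment), optionally
# merged with CDS features from a GFF3 annotation.
#
# ORF sets are plain data.frames with one row per ORF and columns
# orf_id, genome_id, contig_id, strand, start, end, nt_seq, protein, source.
# Coordinates are 1-based inclusive on the forward strand (GFF convention);
# the stop codon is included in start/end/nt_seq and excluded from the
# protein.

.orf_proto <- data.frame(
  orf_id = character(), genome_id = character(), contig_id = character(),
  strand = character(), start = integer(), end = integer(),
  nt_seq = character(), protein = character(), source = character(),
  stringsAsFactors = FALSE
)

.orf_row_id <- function(genome_id, contig_id, start, end, strand) {
  sprintf("%s|%s|%d|%d|%s", genome_id, contig_id, start, end, strand)
}

#' Construct a genome record
#'
#' @param genome_id non-empty identifier (in files, derived from the file
#'   name).
#' @param contigs named character vector of nucleotide sequences over
#'   A/C/G/T/N (upper case).
#' @return object of class `genome_record`.
#' @export
genome_record <- function(genome_id, contigs) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  contigs <- unlist(contigs)
  if (length(contigs) == 0L) stop("genome must contain at least one contig")
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("every contig needs a non-empty id")
  if (anyDuplicated(names(contigs)))
    stop("contig ids must be unique within a genome")
  if (any(!nzchar(contigs)))
    stop("zero-length contig sequence in genome '", genome_id, "'")
  structure(list(genome_id = genome_id, contigs = contigs),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d contig(s), %d bp total\n",
              x$genome_id, length(x$contigs), sum(nchar(x$contigs))))
  invisible(x)
}

#' Read a genome FASTA file
#'
#' Sequences are upcased, `U` is mapped to `T`, and any remaining character
#' outside A/C/G/T/N is replaced by `N` with a warning. The genome id is the
#' file name without its extension.
#'
#' @param path FASTA file of assembled contigs (complete genome or draft).
#' @param genome_id optional override for the id derived from the file name.
#' @return a `genome_record`.
#' @export
read_genome_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot read FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("no sequence records in FASTA file: ", path)
  seqs <- toupper(as.character(set))
  # header up to first whitespace is the contig id
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  if (any(!nzchar(seqs)))
    stop("zero-length sequence record in FASTA file: ", path)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning(sprintf("%d contig(s) in '%s' contain non-ACGTN characters; replaced by N",
                    sum(bad), path))
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  names(seqs) <- ids
  if (is.null(genome_id))
    genome_id <- tools::file_path_sans_ext(basename(path))
  genome_record(genome_id, seqs)
}

# Six-frame segmentation of one already-oriented sequence (one strand).
# Returns ORFs in local (oriented) coordinates.
.scan_frames <- function(seq, min_len_aa) {
  n <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    n_cod <- (n - frame) %/% 3L
    if (n_cod < 1L) next
    starts <- frame + 1L + 3L * (0:(n_cod - 1L))
    codons <- substring(seq, starts, starts + 2L)
    stop_idx <- which(codons %in% STOP_CODONS)
    seg_start <- c(1L, stop_idx + 1L)
    seg_end <- c(stop_idx, n_cod)            # stop codon included in segment
    keep <- seg_start <= seg_end
    seg_start <- seg_start[keep]; seg_end <- seg_end[keep]
    for (k in seq_along(seg_start)) {
      a <- seg_start[k]; b <- seg_end[k]
      has_stop <- codons[b] %in% STOP_CODONS
      coding_end <- b - as.integer(has_stop)
      if (coding_end < a) next
      # start-codon priority: 5'-most ATG, else TTG, else GTG
      r <- NA_integer_
      for (sc in START_CODONS) {
        w <- which(codons[a:coding_end] == sc)
        if (length(w)) { r <- a + w[1L] - 1L; break }
      }
      if (is.na(r)) next
      plen <- coding_end - r + 1L
      if (plen < min_len_aa) next
      p1 <- frame + 1L + 3L * (r - 1L)
      p2 <- frame + 3L * b
      out[[length(out) + 1L]] <- list(p1 = p1, p2 = p2, r = r,
                                      coding_end = coding_end, frame = frame)
    }
  }
  out
}

#' Extract candidate ORFs by six-frame translation
#'
#' Each of the six reading frames of every contig is segmented at stop codons
#' (TAA/TAG/TGA). Within a stop-to-stop segment at most one ORF is emitted:
#' the one starting at the 5'-most ATG, falling back to the first TTG and
#' then the first GTG (prokaryotic start-codon priority). Segments running
#' off a contig end without a stop are kept at their longest codon-multiple
#' extent, tolerating operons split across draft-assembly contigs. The first
#' residue of every protein is reported as M regardless of start codon.
#'
#' @param genome a `genome_record`.
#' @param min_len_aa minimum protein length in amino acids (default 10;
#'   downstream structural length filters dominate, this floor only bounds
#'   the six-frame output volume).
#' @return ORF data.frame (`source = "sixframe"`).
#' @export
extract_orfs <- function(genome, min_len_aa = 10L) {
  stopifnot(inherits(genome, "genome_record"), min_len_aa >= 1L)
  rows <- list()
  for (ci in seq_along(genome$contigs)) {
    contig_id <- names(genome$contigs)[ci]
    fwd <- genome$contigs[[ci]]
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      oriented <- if (strand == "+") fwd else revcomp(fwd)
      hits <- .scan_frames(oriented, min_len_aa)
      for (h in hits) {
        nt <- substring(oriented, h$p1, h$p2)
        if (strand == "+") {
          start <- h$p1; end <- h$p2
        } else {
          start <- L - h$p2 + 1L; end <- L - h$p1 + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          orf_id = .orf_row_id(genome$genome_id, contig_id, start, end, strand),
          genome_id = genome$genome_id, contig_id = contig_id,
          strand = strand, start = start, end = end,
          nt_seq = nt,
          protein = translate_cds(nt),
          source = "sixframe", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty_df(.orf_proto))
  df <- do.call(rbind, rows)
  df <- df[order(df$contig_id, df$start, df$end, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read CDS features from a GFF3 annotation
#'
#' Only `type == "CDS"` features are used; coordinates and strand come from
#' columns 4, 5 and 7 and the nucleotide sequence is cut from the matching
#' contig. Features on unknown contigs, with lengths that are not a multiple
#' of three, or whose translation contains an internal stop are skipped with
#' a warning (draft annotations routinely contain such records).
#'
#' @param path GFF3 file whose seqid column matches the genome's contig ids.
#' @param genome a `genome_record`.
#' @return ORF data.frame (`source = "annotation"`).
#' @export
read_gff_cds <- function(path, genome) {
  stopifnot(inherits(genome, "genome_record"))
  if (!file.exists(path)) stop("GFF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  # everything after a ##FASTA directive is sequence, not features
  rows <- list()
  n_skipped <- 0L
  for (ln in lines) {
    if (startsWith(ln, ">")) break
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) {
      warning("skipping unparseable GFF line: ", substr(ln, 1, 60))
      n_skipped <- n_skipped + 1L
      next
    }
    if (f[3] != "CDS") next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    strand <- f[7]
    if (is.na(start) || is.na(end) || !(strand %in% c("+", "-")) ||
        start > end) {
      warning("skipping unparseable CDS coordinates: ", substr(ln, 1, 60))
      n_skipped <- n_skipped + 1L
      next
    }
    contig_id <- f[1]
    if (!(contig_id %in% names(genome$contigs))) {
      warning("CDS on unknown contig '", contig_id, "' skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    contig <- genome$contigs[[contig_id]]
    if (end > nchar(contig)) {
      warning("CDS beyond contig end skipped (", contig_id, ":", start, "-",
              end, ")")
      n_skipped <- n_skipped + 1L
      next
    }
    len <- end - start + 1L
    if (len %% 3L != 0L) {
      warning("CDS length not a multiple of 3 skipped (", contig_id, ":",
              start, "-", end, ")")
      n_skipped <- n_skipped + 1L
      next
    }
    nt_fwd <- substring(contig, start, end)
    nt <- if (strand == "+") nt_fwd else revcomp(nt_fwd)
    prot <- translate_cds(nt)
    if (grepl("*", prot, fixed = TRUE)) {
      warning("CDS with internal stop skipped (", contig_id, ":", start, "-",
              end, ")")
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      orf_id = .orf_row_id(genome$genome_id, contig_id, start, end, strand),
      genome_id = genome$genome_id, contig_id = contig_id, strand = strand,
      start = start, end = end, nt_seq = nt, protein = prot,
      source = "annotation", stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L)
    message(n_skipped, " GFF feature(s)/line(s) skipped")
  if (!length(rows)) return(empty_df(.orf_proto))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Merge six-frame and annotated ORF sets
#'
#' Two ORFs are the same stop-delimited CDS when they share contig, strand
#' and 3'-end coordinate (alternative starts of one gene must not
#' double-count); for such duplicates the annotation-sourced ORF wins, so a
#' curated non-canonical start overrides the six-frame call.
#'
#' @param sixframe,annotated ORF data.frames from one genome.
#' @return merged ORF data.frame, sorted by contig and start.
#' @export
merge_orf_sets <- function(sixframe, annotated) {
  all <- rbind(annotated, sixframe)   # annotation first => wins on duplicates
  if (nrow(all) == 0L) return(empty_df(.orf_proto))
  end3 <- ifelse(all$strand == "+", all$end, all$start)
  key <- paste(all$contig_id, all$strand, end3, sep = "\r")
  all <- all[!duplicated(key), , drop = FALSE]
  all <- all[order(all$contig_id, all$start, all$end, all$strand), ,
             drop = FALSE]
  rownames(all) <- NULL
  all
}

#' Export an ORF set as amino-acid FASTA
#'
#' Headers follow `genome|contig|start|end|strand|source`.
#'
#' @param orfs ORF data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_orf_fasta <- function(orfs, path) {
  headers <- sprintf("%s|%s|%d|%d|%s|%s", orfs$genome_id, orfs$contig_id,
                     orfs$start, orfs$end, orfs$strand, orfs$source)
  seqs <- orfs$protein
  names(seqs) <- headers
  write_fasta(seqs, path)
}
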