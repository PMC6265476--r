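# Profile-HMM search of candidate ORF proteins.
#
# Scoring is delegated to HMMER3's hmmsearch (the field-standard engine);
# this module owns the surrounding contract: building the query set,
# parsing the per-sequence table, and the bit-score / expected-length /
# dedup filters. The gate is the full-sequence bit score ("overall
# sequence/profile comparison"), not the best single domain.

.hit_proto <- data.frame(
  orf_id = character(), profile = character(), bitscore = numeric(),
  evalue = numeric(), genome_id = character(), contig_id = character(),
  strand = character(), start = integer(), end = integer(),
  protein_len = integer(), stringsAsFactors = FALSE
)

#' Load a profile-HMM library
#'
#' @param path HMMER3 text-format file; may concatenate several profiles.
#' @param expected_lengths optional data.frame from
#'   [parse_expected_lengths()].
#' @return object of class `profile_library` with fields `path`, `names`,
#'   `expected_lengths`.
#' @export
read_profile_library <- function(path, expected_lengths = NULL) {
  if (!file.exists(path)) stop("HMM library not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nm <- sub("^NAME\\s+", "", grep("^NAME\\s+", lines, value = TRUE))
  if (!length(nm))
    stop("no profiles (NAME records) found in HMM library: ", path)
  if (anyDuplicated(nm))
    stop("duplicate profile names in HMM library: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (!is.null(expected_lengths)) {
    stopifnot(all(c("profile", "expected_aa", "max_deviation_aa") %in%
                    names(expected_lengths)))
  }
  structure(list(path = normalizePath(path), names = nm,
                 expected_lengths = expected_lengths),
            class = "profile_library")
}

# Parse a hmmsearch --tblout file into one row per (sequence, profile).
.parse_tblout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(orf_id = character(), profile = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  f <- strsplit(trimws(lines), "[ \t]+")
  data.frame(
    orf_id = vapply(f, `[[`, character(1), 1L),
    profile = vapply(f, `[[`, character(1), 3L),
    evalue = as.numeric(vapply(f, `[[`, character(1), 5L)),
    bitscore = as.numeric(vapply(f, `[[`, character(1), 6L)),
    stringsAsFactors = FALSE)
}

#' Search ORF proteins with a profile-HMM library
#'
#' Runs `hmmsearch` over the ORF protein set and returns one hit per
#' (ORF, profile) pair reported by the engine, carrying the full-sequence
#' bit score and E-value. A permissive reporting threshold is used so that
#' the bit-score gate is applied explicitly by [filter_by_score()].
#'
#' @param orfs ORF data.frame (needs `orf_id` and `protein`).
#' @param library a `profile_library`.
#' @param verbose log engine version and counts.
#' @return hit data.frame with ORF context columns
#'   (`genome_id`, `contig_id`, `strand`, `start`, `end`, `protein_len`).
#' @export
run_profile_search <- function(orfs, library, verbose = FALSE) {
  stopifnot(inherits(library, "profile_library"))
  if (nrow(orfs) == 0L) return(empty_df(.hit_proto))
  if (anyDuplicated(orfs$orf_id)) stop("duplicate orf_id in ORF set")
  hmmsearch <- find_tool("hmmsearch", "profile-HMM search")
  qfa <- tempfile(fileext = ".faa")
  tbl <- tempfile(fileext = ".tbl")
  on.exit(unlink(c(qfa, tbl)), add = TRUE)
  seqs <- orfs$protein
  names(seqs) <- orfs$orf_id
  keep <- nzchar(seqs)
  write_fasta(seqs[keep], qfa)
  status <- system2(hmmsearch,
                    c("--noali", "--tblout", tbl, "-E", "1000",
                      "--domE", "1000", shQuote(library$path), shQuote(qfa)),
                    stdout = if (verbose) "" else FALSE, stderr = FALSE)
  if (!identical(status, 0L) && !identical(status, 0))
    stop("hmmsearch failed (exit status ", status, "); check that '",
         library$path, "' is a valid HMMER3 text-format library")
  raw <- .parse_tblout(tbl)
  if (verbose)
    message("hmmsearch (", tool_version("hmmsearch"), "): ", nrow(raw),
            " raw hit(s) from ", sum(keep), " protein(s)")
  hits <- merge(raw,
                orfs[, c("orf_id", "genome_id", "contig_id", "strand",
                         "start", "end", "protein")],
                by = "orf_id", sort = FALSE)
  hits$protein_len <- nchar(hits$protein)
  hits$protein <- NULL
  hits <- hits[, names(.hit_proto)]
  hits <- hits[order(hits$orf_id, hits$profile), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Filter hits by bit score
#'
#' A candidate counts as a hit only when the full-sequence bit score of the
#' sequence/profile comparison is at least `min_bitscore` (default 20 bits).
#'
#' @param hits hit data.frame.
#' @param min_bitscore threshold in bits; hits with `bitscore >=
#'   min_bitscore` are kept.
#' @return filtered hit data.frame.
#' @export
filter_by_score <- function(hits, min_bitscore = 20) {
  hits[hits$bitscore >= min_bitscore, , drop = FALSE]
}

#' Filter hits by profile-specific expected length
#'
#' For profiles listed in the library's expected-length table, a hit is kept
#' only when its protein length is within `max_deviation_aa` of the
#' profile's expected length; hits of unlisted profiles pass unchanged.
#' Useful when one library mixes conserved families of very different sizes.
#'
#' @param hits hit data.frame (needs `protein_len`).
#' @param library a `profile_library`; a `NULL` or empty expected-length
#'   table makes the filter vacuous.
#' @return filtered hit data.frame.
#' @export
filter_by_expected_length <- function(hits, library) {
  tab <- library$expected_lengths
  if (is.null(tab) || nrow(tab) == 0L || nrow(hits) == 0L) return(hits)
  idx <- match(hits$profile, tab$profile)
  listed <- !is.na(idx)
  dev <- abs(hits$protein_len - tab$expected_aa[idx])
  keep <- !listed | (dev <= tab$max_deviation_aa[idx])
  hits[keep, , drop = FALSE]
}

#' Collapse redundant hits
#'
#' Two reductions prevent one locus from being counted twice: (i) at most
#' one hit per ORF — the highest bit score wins, ties broken by the
#' lexicographically smallest profile name; (ii) among ORFs on the same
#' contig whose intervals overlap by more than half of the shorter ORF
#' (frame-shifted calls of the same locus), only the highest-scoring hit
#' survives.
#'
#' @param hits hit data.frame.
#' @param collapse_overlaps disable the cross-ORF overlap reduction while
#'   keeping the per-ORF one.
#' @return deduplicated hit data.frame.
#' @export
dedupe_hits <- function(hits, collapse_overlaps = TRUE) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(-hits$bitscore, hits$profile, hits$orf_id), ,
               drop = FALSE]
  hits <- hits[!duplicated(hits$orf_id), , drop = FALSE]
  if (collapse_overlaps && nrow(hits) > 1L) {
    keep <- rep(TRUE, nrow(hits))
    for (i in seq_len(nrow(hits))[-1L]) {
      for (j in seq_len(i - 1L)) {
        if (!keep[j]) next
        if (hits$contig_id[j] != hits$contig_id[i] ||
            hits$genome_id[j] != hits$genome_id[i]) next
        ov <- min(hits$end[i], hits$end[j]) -
          max(hits$start[i], hits$start[j]) + 1L
        shorter <- min(hits$end[i] - hits$start[i],
                       hits$end[j] - hits$start[j]) + 1L
        if (ov > 0.5 * shorter) { keep[i] <- FALSE; break }
      }
    }
    hits <- hits[keep, , drop = FALSE]
  }
  hits <- hits[order(hits$genome_id, hits$contig_id, hits$start), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}
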