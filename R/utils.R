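# Shared low-level helpers: sequence arithmetic, codon translation,
# external-tool discovery and cluster label generation.

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "TTG", "GTG")

#' Reverse complement of a nucleotide string
#'
#' Operates on plain character strings over the A/C/G/T/N alphabet (the
#' alphabet guaranteed by [read_genome_fasta()]).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Codon -> amino acid lookup from the standard genetic code (Biostrings).
# Prokaryotic initiation is handled by the callers, which force the first
# residue of a CDS to methionine; any codon containing a non-ACGT character
# translates to "X".
.codon_table <- local({
  tab <- Biostrings::GENETIC_CODE
  names(tab) <- toupper(names(tab))
  tab
})

#' Translate an in-frame coding sequence
#'
#' @param nt nucleotide string, length a multiple of 3, already on the coding
#'   strand.
#' @param first_to_met force the first residue to "M" (prokaryotic initiator).
#' @param strip_stop drop a terminal stop codon if present.
#' @return amino-acid string; ambiguous codons become "X", stops "*".
#' @keywords internal
translate_cds <- function(nt, first_to_met = TRUE, strip_stop = TRUE) {
  nt <- toupper(nt)
  n <- nchar(nt)
  stopifnot(n %% 3 == 0)
  if (n == 0L) return("")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(.codon_table[codons])
  aa[is.na(aa)] <- "X"
  if (strip_stop && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (first_to_met && length(aa) > 0L) aa[1L] <- "M"
  paste(aa, collapse = "")
}

#' Locate an external executable or fail with remediation advice
#' @keywords internal
find_tool <- function(name, purpose) {
  path <- Sys.which(name)
  if (!nzchar(path)) {
    stop(sprintf(
      "external tool '%s' (needed for %s) was not found on PATH. %s",
      name, purpose,
      "Install HMMER3 / NCBI BLAST+ (e.g. via conda: hmmer, blast) and retry."
    ), call. = FALSE)
  }
  unname(path)
}

#' Report the version string of an external tool (for the run log)
#' @keywords internal
tool_version <- function(name) {
  out <- tryCatch(
    suppressWarnings(system2(name, "-h", stdout = TRUE, stderr = TRUE)),
    error = function(e) character(0)
  )
  hit <- grep("HMMER|BLAST|version", out, value = TRUE)
  if (length(hit)) trimws(hit[[1]]) else NA_character_
}

#' Alphabetic cluster labels
#'
#' Clusters are labelled "a","b",... (hits) or "A","B",... (partners) in
#' descending component size; beyond 26 components labels continue "A1",
#' "B1", ..., "A2", ... so they stay short and unique.
#'
#' @param i positive integer index (1-based).
#' @param case "lower" for hit clusters, "upper" for partner clusters.
#' @return character label.
#' @keywords internal
cluster_label <- function(i, case = c("lower", "upper")) {
  case <- match.arg(case)
  alpha <- if (case == "lower") letters else LETTERS
  vapply(i, function(k) {
    stopifnot(k >= 1L)
    if (k <= 26L) return(alpha[k])
    k <- k - 27L
    paste0(alpha[(k %% 26L) + 1L], (k %/% 26L) + 1L)
  }, character(1))
}

#' Write protein sequences as FASTA
#' @param seqs named character vector (names become headers).
#' @param path output file.
#' @return `path`, invisibly.
#' @keywords internal
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  invisible(path)
}

# Empty data.frame templates keep column types stable when a stage
# produces no rows.
empty_df <- function(proto) proto[0L, , drop = FALSE]
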