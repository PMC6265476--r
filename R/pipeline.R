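# End-to-end orchestration of the screen.

#' Screen genomes for conserved gene arrays
#'
#' Runs the full pipeline: six-frame ORF extraction (optionally merged with
#' GFF3 annotation), profile-HMM search with the bit-score gate,
#' profile-specific expected-length filtering, per-ORF/overlap dedup,
#' structural partner filtering, SSN clustering of accepted hits, partners
#' and discarded hits, operon-type labelling and count-matrix tabulation.
#'
#' @param genomes list of `genome_record` objects (or a character vector of
#'   FASTA paths).
#' @param library a `profile_library` (or path to a HMMER3 library file).
#' @param requirements a `structural_requirements`, a `preset`, or a preset
#'   name (`"TA"`, `"RND"`, `"flex"`).
#' @param gff_paths optional named character vector of GFF3 annotation
#'   files, names = genome ids.
#' @param min_bitscore full-sequence bit-score gate (default from the
#'   preset, else 20).
#' @param min_len_aa six-frame ORF floor, aa.
#' @param max_evalue,min_identity SSN edge thresholds.
#' @param run_len ambiguous-nucleotide run threshold.
#' @param near_margin near-miss window for discard reasons, bp.
#' @param allow_antisense permit partners on the opposite strand.
#' @param collapse_overlaps collapse overlapping frame-shifted hits.
#' @param verbose log progress and external tool versions.
#' @return object of class `array_screen`: list with `orfs`, `hits_raw`,
#'   `hits` (post filters/dedup), `operons` (labelled), `discarded`,
#'   `hit_clusters`, `partner_clusters`, `discarded_clusters`, `matrices`,
#'   `params`, `log`.
#' @export
screen_genomes <- function(genomes, library, requirements = "TA",
                           gff_paths = NULL, min_bitscore = NULL,
                           min_len_aa = 10L, max_evalue = 0.01,
                           min_identity = 30, run_len = 8L,
                           near_margin = 100L, allow_antisense = FALSE,
                           collapse_overlaps = TRUE, verbose = FALSE) {
  if (is.character(genomes))
    genomes <- lapply(genomes, read_genome_fasta)
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  if (is.character(library)) library <- read_profile_library(library)
  if (is.character(requirements)) requirements <- load_preset(requirements)
  if (inherits(requirements, "preset")) {
    if (is.null(min_bitscore)) min_bitscore <- requirements$min_bitscore
    req <- requirements$requirements
  } else {
    req <- requirements
  }
  if (is.null(min_bitscore)) min_bitscore <- 20
  validate_requirements(req)
  genome_ids <- vapply(genomes, `[[`, character(1), "genome_id")
  if (anyDuplicated(genome_ids))
    stop("duplicate genome ids: ",
         paste(unique(genome_ids[duplicated(genome_ids)]), collapse = ", "))

  # --- ORFs ------------------------------------------------------------
  orf_sets <- lapply(genomes, function(g) {
    six <- extract_orfs(g, min_len_aa = min_len_aa)
    if (!is.null(gff_paths) && g$genome_id %in% names(gff_paths)) {
      ann <- read_gff_cds(gff_paths[[g$genome_id]], g)
      merge_orf_sets(six, ann)
    } else six
  })
  orfs <- do.call(rbind, orf_sets)
  rownames(orfs) <- NULL
  if (verbose) message(nrow(orfs), " candidate ORF(s) from ",
                       length(genomes), " genome(s)")

  # --- profile search + hit-level filters -------------------------------
  hits_raw <- run_profile_search(orfs, library, verbose = verbose)
  hits <- filter_by_score(hits_raw, min_bitscore)
  hits <- filter_by_expected_length(hits, library)
  hits <- dedupe_hits(hits, collapse_overlaps = collapse_overlaps)
  if (verbose) message(nrow(hits), " hit(s) after score/length/dedup filters")

  # --- structural filter ------------------------------------------------
  res <- filter_operons(hits, orfs, req, run_len = run_len,
                        near_margin = near_margin,
                        allow_antisense = allow_antisense)
  operons <- res$operons
  discarded <- res$discarded

  # --- clustering -------------------------------------------------------
  hit_seqs <- stats::setNames(operons$hit_protein, operons$hit_orf_id)
  hit_seqs <- hit_seqs[!duplicated(names(hit_seqs))]
  hit_assign <- cluster_sequences(hit_seqs, role = "hit",
                                  max_evalue = max_evalue,
                                  min_identity = min_identity)
  nets <- partition_partner_networks(operons, req$orientation)
  partner_assigns <- lapply(names(nets), function(nm) {
    cluster_sequences(nets[[nm]], role = nm, max_evalue = max_evalue,
                      min_identity = min_identity, case = "upper")
  })
  names(partner_assigns) <- names(nets)
  operons <- label_operons(operons, hit_assign, partner_assigns)
  disc_seqs <- stats::setNames(discarded$hit_protein, discarded$hit_orf_id)
  disc_seqs <- disc_seqs[!duplicated(names(disc_seqs))]
  disc_assign <- map_discarded(disc_seqs, hit_seqs, hit_assign,
                               max_evalue = max_evalue,
                               min_identity = min_identity)

  # --- reporting --------------------------------------------------------
  matrices <- tabulate_counts(operons, discarded, disc_assign,
                              genomes = genome_ids,
                              orientation = req$orientation)
  log <- list(
    n_genomes = length(genomes), n_orfs = nrow(orfs),
    n_hits_raw = nrow(hits_raw), n_hits = nrow(hits),
    n_operons = nrow(operons), n_discarded = nrow(discarded),
    hmmsearch_version = tool_version("hmmsearch"),
    blastp_version = tool_version("blastp"))
  params <- list(requirements = req, min_bitscore = min_bitscore,
                 min_len_aa = min_len_aa, max_evalue = max_evalue,
                 min_identity = min_identity, run_len = run_len,
                 near_margin = near_margin,
                 allow_antisense = allow_antisense,
                 collapse_overlaps = collapse_overlaps)
  structure(list(orfs = orfs, hits_raw = hits_raw, hits = hits,
                 operons = operons, discarded = discarded,
                 hit_clusters = hit_assign,
                 partner_clusters = partner_assigns,
                 discarded_clusters = disc_assign,
                 matrices = matrices, params = params, log = log,
                 genome_ids = genome_ids),
            class = "array_screen")
}

#' @export
print.array_screen <- function(x, ...) {
  cat(sprintf(paste0(
    "<array_screen> %d genome(s), %d ORF(s)\n",
    "  hits: %d after filters (%d raw)\n",
    "  accepted operons: %d in %d type(s); discarded hits: %d\n"),
    x$log$n_genomes, x$log$n_orfs, x$log$n_hits, x$log$n_hits_raw,
    x$log$n_operons,
    length(unique(x$operons$operon_type)), x$log$n_discarded))
  invisible(x)
}

#' Write all result files of a screen
#'
#' Emits the four count matrices as CSV, the detailed operon table as TSV,
#' per-matrix iTOL heatmap datasets and a run log.
#'
#' @param screen an `array_screen`.
#' @param dir output directory (created if needed).
#' @param itol_sep separator for iTOL datasets.
#' @return `dir`, invisibly.
#' @export
write_screen_results <- function(screen, dir, itol_sep = "comma") {
  stopifnot(inherits(screen, "array_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(screen$matrices)) {
    m <- screen$matrices[[nm]]
    utils::write.csv(as.data.frame(m),
                     file.path(dir, paste0(nm, "_counts.csv")))
    tryCatch(
      export_itol(m, title = paste0(nm, " copy number"), sep = itol_sep,
                  path = file.path(dir, paste0("itol_", nm, ".txt"))),
      warning = function(w) invisible(NULL))
  }
  write_operon_table(screen$operons, screen$discarded,
                     screen$discarded_clusters,
                     path = file.path(dir, "operons.tsv"))
  log_lines <- c(
    sprintf("genomes: %d", screen$log$n_genomes),
    sprintf("orfs: %d", screen$log$n_orfs),
    sprintf("hits raw/filtered: %d/%d", screen$log$n_hits_raw,
            screen$log$n_hits),
    sprintf("operons/discarded: %d/%d", screen$log$n_operons,
            screen$log$n_discarded),
    sprintf("hmmsearch: %s", screen$log$hmmsearch_version),
    sprintf("blastp: %s", screen$log$blastp_version),
    sprintf("min_bitscore: %s", screen$params$min_bitscore),
    sprintf("orientation: %s", screen$params$requirements$orientation))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
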