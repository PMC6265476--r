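# Structural filtering: partner-gene search around each profile hit.
#
# For every hit that survived the profile-search filters, neighbouring ORFs
# on the same contig and strand are examined on the side(s) required by the
# structural rule set. A hit with a qualifying partner becomes an operon;
# otherwise it is discarded with the most informative reason observed.
#
# "Upstream"/"downstream" are relative to the hit's direction of
# transcription: on the minus strand, upstream means larger forward-strand
# coordinates. Partners must lie on the hit's strand — operonic
# co-transcription, the premise of the screen, requires it — unless
# `allow_antisense` relaxes this.

DISCARD_REASONS <- c("hit_length", "no_partner", "partner_length",
                     "distance", "overlap", "ambiguous")

# precedence when reporting a near-miss (most informative first)
.reason_precedence <- c("ambiguous", "overlap", "distance", "partner_length")

#' Intergenic gap between two genes on one contig
#'
#' With `a` 5' of `b` in forward coordinates, the gap is the number of
#' intervening forward-strand nucleotides, `b$start - a$end - 1`: 0 means
#' abutting genes and a negative value means the genes share `-gap`
#' nucleotides.
#'
#' @param a,b single-row ORF data.frames (or lists) with `contig_id`,
#'   `start`, `end`; `a$start <= b$start`.
#' @return integer gap in bp.
#' @export
gene_gap <- function(a, b) {
  if (!identical(as.character(a$contig_id), as.character(b$contig_id)))
    stop("gene_gap: genes on different contigs")
  if (a$start > b$start) stop("gene_gap: 'a' must be 5' of 'b'")
  as.integer(b$start - a$end - 1L)
}

#' Test for a run of ambiguous nucleotides
#'
#' Partner genes carrying `run_len` (default 8) or more consecutive unknown
#' nucleotides (N or X, case-insensitive) are unreliable assembly regions
#' and are excluded from partner search.
#'
#' @param orf single-row ORF data.frame, or a nucleotide string.
#' @param run_len minimum run length.
#' @return logical.
#' @export
has_ambiguous_run <- function(orf, run_len = 8L) {
  nt <- if (is.character(orf)) orf else orf$nt_seq
  grepl(sprintf("[NXnx]{%d,}", as.integer(run_len)), nt)
}

# Annotate every ORF on the hit's contig/strand with its physical side,
# gap, and qualification status against `req`. Returns a data.frame with
# one row per neighbouring ORF (the hit itself excluded).
.scan_neighbours <- function(hit, orfs, req, run_len = 8L,
                             allow_antisense = FALSE) {
  nb <- orfs[orfs$genome_id == hit$genome_id &
               orfs$contig_id == hit$contig_id &
               orfs$orf_id != hit$orf_id, , drop = FALSE]
  if (!allow_antisense)
    nb <- nb[nb$strand == hit$strand, , drop = FALSE]
  if (nrow(nb) == 0L) {
    nb$side <- character(0); nb$gap_bp <- integer(0)
    nb$protein_len <- integer(0); nb$qualifies <- logical(0)
    nb$fail_reason <- character(0)
    return(nb)
  }
  hit_mid <- (hit$start + hit$end) / 2
  left <- (nb$start + nb$end) / 2 < hit_mid
  gap <- ifelse(left, hit$start - nb$end - 1L, nb$start - hit$end - 1L)
  side <- if (hit$strand == "+") ifelse(left, "upstream", "downstream")
          else ifelse(left, "downstream", "upstream")
  nb$side <- side
  nb$gap_bp <- as.integer(gap)
  nb$protein_len <- nchar(nb$protein)
  min_len <- ifelse(side == "upstream", req$partner_min_aa_up,
                    req$partner_min_aa_down)
  max_len <- ifelse(side == "upstream", req$partner_max_aa_up,
                    req$partner_max_aa_down)
  amb <- has_ambiguous_run(nb$nt_seq, run_len)
  f_overlap <- nb$gap_bp < -req$max_overlap_bp
  f_dist <- nb$gap_bp > req$max_distance_bp
  f_len <- nb$protein_len < min_len | nb$protein_len > max_len
  nb$qualifies <- !amb & !f_overlap & !f_dist & !f_len
  # per-ORF failure label, by precedence
  reason <- rep(NA_character_, nrow(nb))
  reason[f_len] <- "partner_length"
  reason[f_dist] <- "distance"
  reason[f_overlap] <- "overlap"
  reason[amb] <- "ambiguous"
  nb$fail_reason <- reason
  nb
}

.searched_sides <- function(orientation) {
  switch(orientation,
         upstream = "upstream",
         downstream = "downstream",
         either = c("upstream", "downstream"),
         both = c("upstream", "downstream"))
}

#' Qualifying partner candidates around a hit
#'
#' For each side the orientation requires, returns the ORFs on the hit's
#' contig and strand on that side of the hit (in its direction of
#' transcription) whose gap lies in `[-max_overlap_bp, max_distance_bp]`,
#' whose protein length is within the side's bounds, and which carry no
#' ambiguous-nucleotide run. Candidates are sorted by `|gap|` ascending
#' (transcriptional coupling decays with distance), ties by smaller start.
#'
#' @param hit single-row hit data.frame.
#' @param orfs merged ORF set of the hit's genome (or the whole run).
#' @param req a `structural_requirements`.
#' @param run_len ambiguous-run threshold passed to [has_ambiguous_run()].
#' @param allow_antisense also consider ORFs on the opposite strand.
#' @return named list (one element per searched side) of candidate
#'   data.frames with `side` and `gap_bp` columns.
#' @export
candidate_partners <- function(hit, orfs, req, run_len = 8L,
                               allow_antisense = FALSE) {
  nb <- .scan_neighbours(hit, orfs, req, run_len, allow_antisense)
  out <- list()
  for (s in .searched_sides(req$orientation)) {
    cand <- nb[nb$side == s & nb$qualifies, , drop = FALSE]
    cand <- cand[order(abs(cand$gap_bp), cand$start), , drop = FALSE]
    rownames(cand) <- NULL
    out[[s]] <- cand
  }
  out
}

#' Evaluate one hit against the structural requirements
#'
#' The hit protein length is checked first; then the top-ranked candidate
#' on each searched side is taken. Orientation `upstream`/`downstream`
#' requires that side; `both` requires both (three-component array);
#' `either` requires at least one and attaches both when both qualify.
#' A failed hit is discarded with a reason; when no candidate fully
#' qualifies, the most informative near-miss within `near_margin` bp beyond
#' the distance/overlap limits is reported
#' (ambiguous > overlap > distance > partner_length > no_partner).
#'
#' @inheritParams candidate_partners
#' @param near_margin window (bp) beyond the limits in which a failing
#'   neighbour still counts as a near-miss for reason reporting.
#' @return list with `status` ("accepted"/"discarded"), `reason` (NA when
#'   accepted) and `partners` (data.frame, one row per attached side).
#' @export
evaluate_hit <- function(hit, orfs, req, run_len = 8L, near_margin = 100L,
                         allow_antisense = FALSE) {
  validate_requirements(req)
  hlen <- nchar(hit$protein)
  if (hlen < req$hit_min_aa || hlen > req$hit_max_aa)
    return(list(status = "discarded", reason = "hit_length",
                partners = NULL))
  nb <- .scan_neighbours(hit, orfs, req, run_len, allow_antisense)
  sides <- .searched_sides(req$orientation)
  best <- list()
  for (s in sides) {
    cand <- nb[nb$side == s & nb$qualifies, , drop = FALSE]
    if (nrow(cand)) {
      cand <- cand[order(abs(cand$gap_bp), cand$start), , drop = FALSE]
      best[[s]] <- cand[1L, , drop = FALSE]
    }
  }
  ok <- switch(req$orientation,
               upstream = , downstream = length(best) == 1L,
               both = length(best) == 2L,
               either = length(best) >= 1L)
  if (ok) {
    partners <- do.call(rbind, best)
    rownames(partners) <- NULL
    return(list(status = "accepted", reason = NA_character_,
                partners = partners))
  }
  # near-miss reason: failing neighbours within the margin on searched sides
  miss <- nb[nb$side %in% sides & !nb$qualifies &
               nb$gap_bp <= req$max_distance_bp + near_margin &
               nb$gap_bp >= -(req$max_overlap_bp + near_margin), ,
             drop = FALSE]
  reason <- "no_partner"
  if (nrow(miss)) {
    pr <- match(miss$fail_reason, .reason_precedence)
    reason <- .reason_precedence[min(pr, na.rm = TRUE)]
  }
  list(status = "discarded", reason = reason, partners = NULL)
}

.operon_proto <- data.frame(
  operon_id = character(), genome_id = character(), contig_id = character(),
  strand = character(), profile = character(), bitscore = numeric(),
  hit_orf_id = character(), hit_start = integer(), hit_end = integer(),
  hit_protein = character(),
  partner_up_orf_id = character(), partner_up_start = integer(),
  partner_up_end = integer(), partner_up_gap_bp = integer(),
  partner_up_protein = character(), partner_up_is_hit = logical(),
  partner_down_orf_id = character(), partner_down_start = integer(),
  partner_down_end = integer(), partner_down_gap_bp = integer(),
  partner_down_protein = character(), partner_down_is_hit = logical(),
  stringsAsFactors = FALSE
)

.discard_proto <- data.frame(
  genome_id = character(), contig_id = character(), strand = character(),
  profile = character(), bitscore = numeric(), hit_orf_id = character(),
  hit_start = integer(), hit_end = integer(), hit_protein = character(),
  reason = character(), stringsAsFactors = FALSE
)

#' Apply the structural filter to a whole hit set
#'
#' Evaluates every hit with [evaluate_hit()] and partitions the input into
#' accepted operons and discarded hits; the partition is exact
#' (`nrow(operons) + nrow(discarded) == nrow(hits)`). A partner that is
#' itself a hit of some profile (e.g. tandem toxins) is allowed and flagged
#' in `partner_*_is_hit`.
#'
#' @param hits deduplicated hit data.frame (any number of genomes).
#' @param orfs merged ORF set covering those genomes.
#' @param req a `structural_requirements`.
#' @inheritParams evaluate_hit
#' @return list with data.frames `operons` and `discarded`.
#' @export
filter_operons <- function(hits, orfs, req, run_len = 8L, near_margin = 100L,
                           allow_antisense = FALSE) {
  ops <- list(); dis <- list()
  orf_lookup <- orfs[match(hits$orf_id, orfs$orf_id), , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    hit <- orf_lookup[i, , drop = FALSE]
    hit$profile <- hits$profile[i]
    hit$bitscore <- hits$bitscore[i]
    verdict <- evaluate_hit(hit, orfs, req, run_len, near_margin,
                            allow_antisense)
    if (verdict$status == "accepted") {
      row <- data.frame(
        operon_id = paste0("op|", hit$orf_id),
        genome_id = hit$genome_id, contig_id = hit$contig_id,
        strand = hit$strand, profile = hit$profile, bitscore = hit$bitscore,
        hit_orf_id = hit$orf_id, hit_start = hit$start, hit_end = hit$end,
        hit_protein = hit$protein,
        partner_up_orf_id = NA_character_, partner_up_start = NA_integer_,
        partner_up_end = NA_integer_, partner_up_gap_bp = NA_integer_,
        partner_up_protein = NA_character_, partner_up_is_hit = NA,
        partner_down_orf_id = NA_character_, partner_down_start = NA_integer_,
        partner_down_end = NA_integer_, partner_down_gap_bp = NA_integer_,
        partner_down_protein = NA_character_, partner_down_is_hit = NA,
        stringsAsFactors = FALSE)
      for (j in seq_len(nrow(verdict$partners))) {
        p <- verdict$partners[j, ]
        pre <- if (p$side == "upstream") "partner_up_" else "partner_down_"
        row[[paste0(pre, "orf_id")]] <- p$orf_id
        row[[paste0(pre, "start")]] <- p$start
        row[[paste0(pre, "end")]] <- p$end
        row[[paste0(pre, "gap_bp")]] <- p$gap_bp
        row[[paste0(pre, "protein")]] <- p$protein
        row[[paste0(pre, "is_hit")]] <- p$orf_id %in% hits$orf_id
      }
      ops[[length(ops) + 1L]] <- row
    } else {
      dis[[length(dis) + 1L]] <- data.frame(
        genome_id = hit$genome_id, contig_id = hit$contig_id,
        strand = hit$strand, profile = hit$profile, bitscore = hit$bitscore,
        hit_orf_id = hit$orf_id, hit_start = hit$start, hit_end = hit$end,
        hit_protein = hit$protein, reason = verdict$reason,
        stringsAsFactors = FALSE)
    }
  }
  operons <- if (length(ops)) do.call(rbind, ops) else empty_df(.operon_proto)
  discarded <- if (length(dis)) do.call(rbind, dis)
               else empty_df(.discard_proto)
  rownames(operons) <- NULL; rownames(discarded) <- NULL
  list(operons = operons, discarded = discarded)
}
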