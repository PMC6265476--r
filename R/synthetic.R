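# Deterministic synthetic genomes with planted gene arrays.
#
# The generator emulates the TA-preset world: two-gene arrays (one
# profile-matched "hit" gene, one partner) planted in inert spacer DNA at
# controlled gap/overlap/orientation/length, including every violation
# class the structural filter tests, plus toy protein families from which
# profile HMMs can be built. Everything is a pure function of the seed.
#
# Three sequence-design rules keep the planted truth table exact:
#  * spacers, guards and gap filler are drawn from {A,T} only — every
#    permitted start codon contains G, so inter-gene DNA can contain no ORF
#    at all;
#  * gene codons never end in T and the generated proteins avoid W and C,
#    which provably excludes ATG/TTG/GTG from the two alternative
#    same-strand frames inside genes (a start codon spanning a codon
#    junction needs either a codon ending in T before G, or a codon
#    starting "TG");
#  * antisense partner genes additionally use C-free codons, so their
#    reverse complement (which faces the hit's strand) contains no G and
#    therefore no start codon.
# A post-hoc check per planted cassette verifies that exactly the intended
# ORFs are recovered and that no stray same-strand ORF sits in the hit's
# partner-search window; failures regenerate deterministically.

.GUARD <- "TTAATTAATTAA"  # stop codons in all six frames, G/C-free

# TA-preset constants: the stated world of the generator
.TA <- list(hit_min = 30L, hit_max = 200L, p_min = 50L, p_max = 150L,
            dist = 50L, ovl = 20L)

# amino-acid alphabets (see header): standard drops W and C; noC is
# additionally C-free at the codon level for antisense partners
.aa_standard <- c("A", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                  "P", "Q", "R", "S", "T", "V", "Y")
.aa_noc <- c("E", "G", "I", "K", "L", "R", "V")

# conservative substitution groups over the standard alphabet
.aa_groups <- list(c("I", "L", "V", "M"), c("F", "Y"), c("K", "R", "H"),
                   c("D", "E"), c("S", "T"), c("N", "Q"), c("A", "G"),
                   c("P"))

.bt_codons <- local({
  tab <- Biostrings::GENETIC_CODE
  by_aa <- split(names(tab), unname(tab))
  std <- lapply(by_aa, function(cs) cs[!endsWith(cs, "T") &
                                         !startsWith(cs, "TG")])
  noc <- lapply(std, function(cs) cs[!grepl("C", cs)])
  list(standard = std, noC = noc)
})

.filler <- function(n) {
  if (n <= 0L) return("")
  substr(strrep("TTAA", n %/% 4L + 1L), 1L, n)
}

.spacer <- function(n) {
  paste(sample(c("T", "A"), n, replace = TRUE), collapse = "")
}

.backtranslate <- function(protein, alphabet = "standard") {
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(seq_along(aas), function(i) {
    if (i == 1L && aas[1L] == "M") return("ATG")
    cs <- .bt_codons[[alphabet]][[aas[i]]]
    if (is.null(cs) || !length(cs))
      stop("no permitted codon for amino acid '", aas[i], "'")
    cs[sample.int(length(cs), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

.valid_gene <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L || substr(nt, 1, 3) != "ATG") return(FALSE)
  prot <- translate_cds(nt, first_to_met = FALSE, strip_stop = FALSE)
  p <- strsplit(prot, "", fixed = TRUE)[[1]]
  p[length(p)] == "*" && !any(p[-length(p)] == "*")
}

#' Generate a random synthetic gene
#'
#' Starts with ATG, ends with TAA, contains no in-frame internal stop, and
#' is deterministic under the seed. Codon choice follows the generator's
#' start-codon-suppression rules (see the package vignette), so the gene
#' contributes no spurious ORFs in alternative same-strand frames.
#'
#' @param length_aa protein length including the initiator M (at least 2).
#' @param seed integer seed.
#' @param alphabet `"standard"` or `"noC"` (for antisense placement).
#' @return nucleotide string of length `3 * length_aa + 3`.
#' @export
synth_gene <- function(length_aa, seed, alphabet = "standard") {
  stopifnot(length_aa >= 2L)
  withr::with_seed(seed, {
    alpha <- if (alphabet == "noC") .aa_noc else .aa_standard
    protein <- paste(c("M", sample(alpha, length_aa - 1L, replace = TRUE)),
                     collapse = "")
    paste0(.backtranslate(protein, alphabet), "TAA")
  })
}

#' Generate a mutated protein family from a base gene
#'
#' Produces `n_variants` copies of the base gene's protein with independent
#' conservative substitutions (within physicochemical groups; stops and
#' the initiator are never touched), plus back-translated variant genes.
#' All variants have equal length, so the protein set is itself an ungapped
#' alignment ready for profile building.
#'
#' @param base_gene nucleotide string from [synth_gene()].
#' @param n_variants number of family members.
#' @param sub_rate per-site substitution probability (at most 0.3).
#' @param seed integer seed.
#' @return list with `proteins` and `genes` (named character vectors) and
#'   `base_protein`.
#' @export
make_family <- function(base_gene, n_variants, sub_rate, seed) {
  stopifnot(sub_rate >= 0, sub_rate <= 0.3, n_variants >= 1L)
  base_protein <- translate_cds(base_gene)
  group_of <- stats::setNames(
    rep(seq_along(.aa_groups), lengths(.aa_groups)), unlist(.aa_groups))
  withr::with_seed(seed, {
    proteins <- vapply(seq_len(n_variants), function(v) {
      aas <- strsplit(base_protein, "", fixed = TRUE)[[1]]
      for (i in seq_along(aas)[-1L]) {
        gi <- group_of[aas[i]]
        if (is.na(gi)) next
        members <- setdiff(.aa_groups[[gi]], aas[i])
        if (length(members) && stats::runif(1) < sub_rate)
          aas[i] <- sample(members, 1L)
      }
      paste(aas, collapse = "")
    }, character(1))
    names(proteins) <- sprintf("v%02d", seq_len(n_variants))
    genes <- vapply(proteins, function(p) {
      paste0(.backtranslate(p, "standard"), "TAA")
    }, character(1))
    list(proteins = proteins, genes = genes, base_protein = base_protein)
  })
}

#' Write a family's protein alignment as FASTA
#' @param family list from [make_family()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_family_alignment <- function(family, path) {
  write_fasta(family$proteins, path)
}

#' Build a profile-HMM library from protein families
#'
#' Runs `hmmbuild` on each family's ungapped protein alignment and
#' concatenates the resulting profiles into one HMMER3 text-format library.
#'
#' @param families named list of [make_family()] results; names become
#'   profile names.
#' @param path output library file.
#' @return a `profile_library` for the written file.
#' @export
build_profile_library <- function(families, path) {
  hmmbuild <- find_tool("hmmbuild", "profile construction from alignments")
  dir <- tempfile("hmmbuild")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  parts <- character(0)
  for (nm in names(families)) {
    aln <- file.path(dir, paste0(nm, ".afa"))
    write_family_alignment(families[[nm]], aln)
    hmm <- file.path(dir, paste0(nm, ".hmm"))
    ok <- system2(hmmbuild, c("--amino", "-n", nm, shQuote(hmm),
                              shQuote(aln)),
                  stdout = FALSE, stderr = FALSE)
    if (!identical(ok, 0L) && !identical(ok, 0))
      stop("hmmbuild failed for family '", nm, "'")
    parts <- c(parts, readLines(hmm, warn = FALSE))
  }
  writeLines(parts, path)
  read_profile_library(path)
}

#' Specify one planted gene array
#'
#' The default geometry (100-aa hit, 90-aa partner, 30 bp gap, downstream,
#' plus strand) satisfies every TA-preset constraint; a `violation` tag
#' perturbs exactly one constraint to one unit past its limit (distance 51,
#' overlap -22 — see the vignette for why -21 cannot exist on one strand —
#' partner 49/151 aa, hit 29/201 aa) or plants an orphan, an
#' ambiguous-nucleotide partner, or an antisense partner. Explicit
#' arguments override the defaults, so boundary fixtures (gap 50, overlap
#' -20, lengths 30/200/50/150) are expressed with `violation = "none"`.
#'
#' @param family profile family name the hit gene is drawn from.
#' @param violation one of `"none"`, `"distance"`, `"overlap"`,
#'   `"partner_short"`, `"partner_long"`, `"hit_short"`, `"hit_long"`,
#'   `"orphan"`, `"ambiguous"`, `"antisense"`.
#' @param side `"upstream"`, `"downstream"` or `"both_sides"` (relative to
#'   the hit's transcription; `both_sides` only with `violation = "none"`).
#' @param strand `"+"` or `"-"` (of the final contig).
#' @param hit_len_aa,partner_len_aa,gap_bp geometry overrides.
#' @return one-row data.frame (a plant specification) including the
#'   expected pipeline outcome.
#' @export
plant_spec <- function(family = "famA", violation = "none",
                       side = "downstream", strand = "+",
                       hit_len_aa = 100L, partner_len_aa = 90L,
                       gap_bp = 30L) {
  violation <- match.arg(violation,
                         c("none", "distance", "overlap", "partner_short",
                           "partner_long", "hit_short", "hit_long", "orphan",
                           "ambiguous", "antisense"))
  side <- match.arg(side, c("downstream", "upstream", "both_sides"))
  stopifnot(strand %in% c("+", "-"))
  if (side == "both_sides" && violation != "none")
    stop("both_sides plants support violation = 'none' only")
  if (violation == "antisense" && gap_bp < 0L)
    stop("antisense plants require a non-negative gap")
  if (side == "both_sides" && gap_bp < 0L)
    stop("both_sides plants require a non-negative gap")
  switch(violation,
         distance = { gap_bp <- .TA$dist + 1L },
         overlap = { gap_bp <- -(.TA$ovl + 2L) },  # -21 unrealisable
         partner_short = { partner_len_aa <- .TA$p_min - 1L },
         partner_long = { partner_len_aa <- .TA$p_max + 1L },
         hit_short = { hit_len_aa <- .TA$hit_min - 1L },
         hit_long = { hit_len_aa <- .TA$hit_max + 1L },
         NULL)
  spec <- data.frame(family = family, violation = violation, side = side,
                     strand = strand, hit_len_aa = as.integer(hit_len_aa),
                     partner_len_aa = as.integer(partner_len_aa),
                     gap_bp = as.integer(gap_bp), stringsAsFactors = FALSE)
  spec$expected <- expected_outcome(spec)
  spec
}

#' Expected pipeline outcome of a plant specification
#'
#' Computable from the specification alone, mirroring the filter's decision
#' order and near-miss precedence under the TA preset: hit length first,
#' then missing/antisense partner, then ambiguous > overlap > distance >
#' partner length.
#'
#' @param spec plant data.frame (one or more rows).
#' @return character vector: `"accepted"` or `"discarded:<reason>"`.
#' @export
expected_outcome <- function(spec) {
  vapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    if (s$hit_len_aa < .TA$hit_min || s$hit_len_aa > .TA$hit_max)
      return("discarded:hit_length")
    if (s$violation == "orphan" || s$violation == "antisense")
      return("discarded:no_partner")
    if (s$violation == "ambiguous") return("discarded:ambiguous")
    if (s$gap_bp < -.TA$ovl) return("discarded:overlap")
    if (s$gap_bp > .TA$dist) return("discarded:distance")
    if (s$partner_len_aa < .TA$p_min || s$partner_len_aa > .TA$p_max)
      return("discarded:partner_length")
    "accepted"
  }, character(1))
}

#' Grid of plant specifications
#'
#' Crosses violations, strands and sides into a flat plant table;
#' `both_sides` is kept only for `violation = "none"`.
#'
#' @param families family names, recycled across the grid.
#' @param violations,strands,sides factors to cross.
#' @param reps repetitions of the full grid.
#' @return plant data.frame.
#' @export
plant_grid <- function(families = "famA",
                       violations = c("none", "distance", "overlap",
                                      "partner_short", "partner_long",
                                      "hit_short", "hit_long", "orphan",
                                      "ambiguous", "antisense"),
                       strands = c("+", "-"),
                       sides = c("downstream", "upstream"),
                       reps = 1L) {
  g <- expand.grid(violation = violations, strand = strands, side = sides,
                   rep = seq_len(reps), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(g)), function(i) {
    plant_spec(family = families[((i - 1L) %% length(families)) + 1L],
               violation = g$violation[i], side = g$side[i],
               strand = g$strand[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- cassette construction --------------------------------------------

# Force an overlap of k bp between hit and partner on one strand.
# Returns NULL when this randomisation fails; the caller retries.
.force_overlap <- function(hit_nt, partner_nt, k, side) {
  if (k %% 3L == 0L || k == 2L || k == 5L)
    stop("overlap of ", k, " bp is unrealisable for same-strand gene pairs")
  nh <- nchar(hit_nt); np <- nchar(partner_nt)
  if (side == "downstream") {
    # shared region = hit tail = partner head; hit's stop sits at partner
    # nt k-2..k
    if (k == 1L) {
      # hit stop ends in A = partner's leading A
      if (!endsWith(hit_nt, "A")) return(NULL)
    } else if (k == 4L) {
      substr(partner_nt, 4L, 4L) <- "A"   # hit stop becomes TGA
    } else {
      substr(partner_nt, k - 2L, k) <- "TAA"
    }
    if (!.valid_gene(partner_nt)) return(NULL)
    hit_mod <- paste0(substr(hit_nt, 1L, nh - k), substr(partner_nt, 1L, k))
    if (!.valid_gene(hit_mod)) return(NULL)
    list(hit = hit_mod, partner = partner_nt)
  } else {
    # upstream: shared region = partner tail = hit head; partner's stop
    # sits at hit nt k-2..k
    if (k == 1L) {
      # partner stop must end in A; hit nt1 is A
      if (!endsWith(partner_nt, "A")) return(NULL)
      partner_mod <- partner_nt
    } else {
      if (k == 4L) substr(hit_nt, 4L, 4L) <- "A"   # partner stop = TGA
      else substr(hit_nt, k - 2L, k) <- "TAA"
      if (!.valid_gene(hit_nt)) return(NULL)
      partner_mod <- paste0(substr(partner_nt, 1L, np - k),
                            substr(hit_nt, 1L, k))
      if (!.valid_gene(partner_mod)) return(NULL)
    }
    list(hit = hit_nt, partner = partner_mod)
  }
}

# Assemble one plant cassette in its transcription orientation.
# Returns list(seq, hit = c(s,e), partner_up, partner_down, partner_strand)
# with 1-based local coordinates, or NULL if this randomisation failed.
.cassette_attempt <- function(spec, hit_nt, seed) {
  withr::with_seed(seed, {
    glen <- nchar(.GUARD)
    mk_partner <- function() {
      alphabet <- if (spec$violation == "antisense") "noC" else "standard"
      nt <- paste0(.backtranslate(
        paste(c("M", sample(if (alphabet == "noC") .aa_noc else .aa_standard,
                            spec$partner_len_aa - 1L, replace = TRUE)),
              collapse = ""), alphabet), "TAA")
      if (spec$violation == "ambiguous") {
        mid <- 3L * (spec$partner_len_aa %/% 2L) + 1L
        substr(nt, mid, mid + 7L) <- "NNNNNNNN"
      }
      nt
    }
    place <- function(parts) {
      # parts: list of list(nt, role) in 5'->3' order with gaps between
      seq <- .GUARD; pos <- glen
      coords <- list()
      for (p in parts) {
        if (!is.null(p$gap_before)) {
          if (p$gap_before >= 0L) {
            seq <- paste0(seq, .filler(p$gap_before))
            pos <- pos + p$gap_before
          } else {
            k <- -p$gap_before
            seq <- substr(seq, 1L, nchar(seq) - k)
            pos <- pos - k
          }
        }
        coords[[p$role]] <- c(pos + 1L, pos + nchar(p$nt))
        seq <- paste0(seq, p$nt)
        pos <- pos + nchar(p$nt)
      }
      list(seq = paste0(seq, .GUARD), coords = coords)
    }
    if (spec$violation == "orphan") {
      res <- place(list(list(nt = hit_nt, role = "hit")))
      return(list(seq = res$seq, coords = res$coords,
                  partner_strand = NA_character_))
    }
    partner_nt <- mk_partner()
    k <- if (spec$gap_bp < 0L) -spec$gap_bp else 0L
    antis <- spec$violation == "antisense"
    if (k > 0L && !antis) {
      side_eff <- if (spec$side == "both_sides") "downstream" else spec$side
      if (side_eff == "upstream") {
        # the shared region is the hit's head: re-code it per attempt, with
        # conservative residue swaps, so the partner-frame stop constraint
        # can always be met (some residues, e.g. Ile, admit only A-leading
        # codons and would otherwise force a stop in the partner's frame;
        # the downstream construction similarly rewrites the hit's tail)
        ncod <- min(k %/% 3L + 3L, nchar(hit_nt) %/% 3L - 1L)
        aas <- strsplit(translate_cds(substr(hit_nt, 1L, 3L * ncod),
                                      strip_stop = FALSE), "")[[1]]
        group_of <- stats::setNames(
          rep(seq_along(.aa_groups), lengths(.aa_groups)),
          unlist(.aa_groups))
        for (i in seq_along(aas)[-1L]) {
          gi <- group_of[aas[i]]
          if (!is.na(gi)) aas[i] <- sample(.aa_groups[[gi]], 1L)
        }
        hit_nt <- paste0(.backtranslate(paste(aas, collapse = ""),
                                        "standard"),
                         substr(hit_nt, 3L * ncod + 1L, nchar(hit_nt)))
      }
      forced <- .force_overlap(hit_nt, partner_nt, k, side_eff)
      if (is.null(forced)) return(NULL)
      hit_nt <- forced$hit; partner_nt <- forced$partner
    }
    p_piece <- if (antis) revcomp(partner_nt) else partner_nt
    parts <- switch(
      spec$side,
      downstream = list(
        list(nt = hit_nt, role = "hit"),
        list(nt = p_piece, role = "partner_down", gap_before = spec$gap_bp)),
      upstream = list(
        list(nt = p_piece, role = "partner_up"),
        list(nt = hit_nt, role = "hit", gap_before = spec$gap_bp)),
      both_sides = {
        p2 <- mk_partner()
        list(list(nt = p2, role = "partner_up"),
             list(nt = hit_nt, role = "hit", gap_before = spec$gap_bp),
             list(nt = p_piece, role = "partner_down",
                  gap_before = spec$gap_bp))
      })
    res <- place(parts)
    list(seq = res$seq, coords = res$coords,
         partner_strand = if (antis) "-" else "+")
  })
}

# Verify a cassette in its transcription orientation: the planted ORFs are
# recovered exactly and no stray same-strand ORF sits in the hit's
# partner-search window (TA limits + near margin).
.validate_cassette <- function(cas, min_len_aa = 10L, near_margin = 100L) {
  g <- genome_record("cas", c(c1 = cas$seq))
  orfs <- extract_orfs(g, min_len_aa = min_len_aa)
  expect_one <- function(s, e, strand) {
    any(orfs$start == s & orfs$end == e & orfs$strand == strand)
  }
  hc <- cas$coords$hit
  if (!expect_one(hc[1], hc[2], "+")) return(FALSE)
  planted <- list(c(hc, NA))
  for (role in c("partner_up", "partner_down")) {
    pc <- cas$coords[[role]]
    if (is.null(pc)) next
    str <- cas$partner_strand
    if (!expect_one(pc[1], pc[2], str)) return(FALSE)
    planted <- c(planted, list(pc))
  }
  planted_key <- vapply(planted, function(p) paste(p[1], p[2]), character(1))
  hit_mid <- (hc[1] + hc[2]) / 2
  for (i in seq_len(nrow(orfs))) {
    if (orfs$strand[i] != "+") next
    if (paste(orfs$start[i], orfs$end[i]) %in% planted_key) next
    left <- (orfs$start[i] + orfs$end[i]) / 2 < hit_mid
    gap <- if (left) hc[1] - orfs$end[i] - 1L else orfs$start[i] - hc[2] - 1L
    if (gap <= .TA$dist + near_margin && gap >= -(.TA$ovl + near_margin))
      return(FALSE)
  }
  TRUE
}

#' Generate a synthetic dataset of genomes with planted arrays
#'
#' Builds one mutated protein family per family name referenced by the
#' plants (100-aa base gene, 20 variants, 5% conservative substitution so
#' truncated 29-aa hits still score well above the 20-bit gate), assigns
#' plants to genomes round-robin, and assembles each genome as inert
#' spacer DNA with one cassette per plant. Hit genes are family variants
#' adjusted to the requested length (truncation / random-tail extension).
#' Output is byte-identical under a fixed seed.
#'
#' @param n_genomes number of genomes.
#' @param plants plant data.frame from [plant_spec()] / [plant_grid()].
#' @param seed integer master seed.
#' @param spacer_len_bp inert spacer between cassettes (at least 160 so
#'   that partner-search windows cannot reach a neighbouring cassette).
#' @param family_size,family_sub_rate family generation parameters.
#' @return list with `genomes` (list of `genome_record`), `truth`
#'   (data.frame: one row per plant with planted coordinates and expected
#'   outcome), `families` and `plants`.
#' @export
generate_dataset <- function(n_genomes, plants, seed, spacer_len_bp = 200L,
                             family_size = 20L, family_sub_rate = 0.05) {
  stopifnot(n_genomes >= 1L, nrow(plants) >= 1L, spacer_len_bp >= 160L)
  fam_names <- sort(unique(plants$family))
  families <- lapply(seq_along(fam_names), function(i) {
    base <- synth_gene(100L, seed = seed + 17L * i)
    make_family(base, n_variants = family_size, sub_rate = family_sub_rate,
                seed = seed + 31L * i)
  })
  names(families) <- fam_names

  adjust_hit <- function(variant_nt, len_aa, sub_seed) {
    base_len <- nchar(variant_nt) %/% 3L - 1L
    if (len_aa == base_len) return(variant_nt)
    if (len_aa < base_len)
      return(paste0(substr(variant_nt, 1L, 3L * len_aa), "TAA"))
    extra <- len_aa - base_len
    withr::with_seed(sub_seed, {
      tail_aa <- paste(sample(.aa_standard, extra, replace = TRUE),
                       collapse = "")
      tail_nt <- .backtranslate(paste0("G", tail_aa), "standard")
      # drop the dummy leading codon used to satisfy backtranslate's
      # initiator handling
      paste0(substr(variant_nt, 1L, 3L * base_len),
             substr(tail_nt, 4L, nchar(tail_nt)), "TAA")
    })
  }

  genome_of <- ((seq_len(nrow(plants)) - 1L) %% n_genomes) + 1L
  genome_ids <- sprintf("genome%03d", seq_len(n_genomes))
  contig_id <- "c1"
  seqs <- stats::setNames(vector("list", n_genomes), genome_ids)
  truth_rows <- list()
  for (gi in seq_len(n_genomes)) {
    withr::with_seed(seed + 101L * gi, {
      pieces <- .spacer(spacer_len_bp)
      offset <- spacer_len_bp
      for (pi in which(genome_of == gi)) {
        spec <- plants[pi, , drop = FALSE]
        fam <- families[[spec$family]]
        variant_i <- ((pi - 1L) %% length(fam$genes)) + 1L
        cas <- NULL
        for (attempt in 0:499) {
          aseed <- (seed + 7919L * pi + 613L * attempt) %% 2100000000L
          # cycle variants across attempts: overlap constructions constrain
          # the hit's own codons, so a fresh codon randomisation may be
          # needed for a consistent gene pair
          v_try <- ((variant_i - 1L + attempt) %% length(fam$genes)) + 1L
          hit_nt <- adjust_hit(fam$genes[[v_try]], spec$hit_len_aa,
                               aseed + 1L)
          try_cas <- .cassette_attempt(spec, hit_nt, aseed)
          if (!is.null(try_cas) && .validate_cassette(try_cas)) {
            cas <- try_cas
            break
          }
        }
        if (is.null(cas))
          stop("could not realise plant ", pi, " (", spec$violation,
               "); specification may be unrealisable")
        L <- nchar(cas$seq)
        flip <- spec$strand == "-"
        final_seq <- if (flip) revcomp(cas$seq) else cas$seq
        mapc <- function(co) {
          if (is.null(co)) return(c(NA_integer_, NA_integer_))
          if (flip) c(L - co[2] + 1L, L - co[1] + 1L) else co
        }
        hit_c <- mapc(cas$coords$hit) + offset
        up_c <- mapc(cas$coords$partner_up) + offset
        dn_c <- mapc(cas$coords$partner_down) + offset
        p_strand <- cas$partner_strand
        if (!is.na(p_strand) && flip)
          p_strand <- if (p_strand == "+") "-" else "+"
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          plant_id = pi, genome_id = genome_ids[gi], contig_id = contig_id,
          family = spec$family, violation = spec$violation,
          side = spec$side, strand = spec$strand,
          hit_len_aa = spec$hit_len_aa,
          partner_len_aa = spec$partner_len_aa, gap_bp = spec$gap_bp,
          hit_start = hit_c[1], hit_end = hit_c[2],
          partner_up_start = up_c[1], partner_up_end = up_c[2],
          partner_down_start = dn_c[1], partner_down_end = dn_c[2],
          partner_strand = p_strand,
          expected = spec$expected, stringsAsFactors = FALSE)
        pieces <- paste0(pieces, final_seq, .spacer(spacer_len_bp))
        offset <- offset + L + spacer_len_bp
      }
      seqs[[gi]] <- stats::setNames(pieces, contig_id)
    })
  }
  genomes <- lapply(genome_ids, function(id) genome_record(id, seqs[[id]]))
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(genomes = genomes, truth = truth, families = families,
       plants = plants)
}

#' Write a synthetic dataset to disk
#'
#' Emits one FASTA per genome, the truth table as TSV, one aligned protein
#' FASTA per family, and optionally a GFF3 of the planted genes per genome
#' (for annotation-merge tests).
#'
#' @param dataset list from [generate_dataset()].
#' @param dir output directory.
#' @param gff also write planted-gene GFF3 files.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, gff = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in dataset$genomes) {
    fa <- file.path(dir, paste0(g$genome_id, ".fasta"))
    con <- file(fa, "wt")
    for (i in seq_along(g$contigs))
      writeLines(c(paste0(">", names(g$contigs)[i]), g$contigs[[i]]), con)
    close(con)
  }
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(dataset$families))
    write_family_alignment(dataset$families[[nm]],
                           file.path(dir, paste0(nm, ".afa")))
  if (gff) {
    tr <- dataset$truth
    for (g in dataset$genomes) {
      rows <- tr[tr$genome_id == g$genome_id, , drop = FALSE]
      lines <- "##gff-version 3"
      for (i in seq_len(nrow(rows))) {
        r <- rows[i, ]
        cds <- function(s, e, strand, id) {
          sprintf("%s\tsynthetic\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                  r$contig_id, s, e, strand, id)
        }
        lines <- c(lines, cds(r$hit_start, r$hit_end, r$strand,
                              paste0("hit", r$plant_id)))
        if (!is.na(r$partner_up_start))
          lines <- c(lines, cds(r$partner_up_start, r$partner_up_end,
                                r$partner_strand,
                                paste0("pup", r$plant_id)))
        if (!is.na(r$partner_down_start))
          lines <- c(lines, cds(r$partner_down_start, r$partner_down_end,
                                r$partner_strand,
                                paste0("pdn", r$plant_id)))
      }
      writeLines(lines, file.path(dir, paste0(g$genome_id, ".gff")))
    }
  }
  invisible(dir)
}
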