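# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

# a conserved 100-aa toy family + its HMM library (needs hmmbuild)
fix_family <- function() {
  if (is.null(.fix$family)) {
    base <- synth_gene(100L, seed = 4242L)
    .fix$family <- make_family(base, n_variants = 20L, sub_rate = 0.05,
                               seed = 777L)
  }
  .fix$family
}

fix_library <- function() {
  if (is.null(.fix$library)) {
    path <- file.path(tempdir(), "fix_famA.hmm")
    .fix$library <- build_profile_library(list(famA = fix_family()), path)
  }
  .fix$library
}

# fabricated ORF rows for rule-level tests (sequence content synthetic:
# protein is a poly-K of the requested length, nt a poly-A of matching
# length — geometry, not biology, is under test)
fake_orf <- function(contig = "c1", strand = "+", start, plen,
                     genome = "g1", nt = NULL, end = NULL) {
  if (is.null(end)) end <- start + 3L * (plen + 1L) - 1L
  if (is.null(nt)) nt <- strrep("A", end - start + 1L)
  data.frame(
    orf_id = sprintf("%s|%s|%d|%d|%s", genome, contig, start, end, strand),
    genome_id = genome, contig_id = contig, strand = strand,
    start = as.integer(start), end = as.integer(end), nt_seq = nt,
    protein = strrep("K", plen), source = "sixframe",
    stringsAsFactors = FALSE)
}

fake_hit <- function(orf, profile = "famA", bitscore = 50) {
  data.frame(orf_id = orf$orf_id, profile = profile, bitscore = bitscore,
             evalue = 1e-10, genome_id = orf$genome_id,
             contig_id = orf$contig_id, strand = orf$strand,
             start = orf$start, end = orf$end,
             protein_len = nchar(orf$protein), stringsAsFactors = FALSE)
}

# random A/C/G/T contig
random_contig <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

write_tmp_fasta <- function(records, ext = ".fasta") {
  path <- tempfile(fileext = ext)
  con <- file(path, "wt")
  for (nm in names(records)) writeLines(c(paste0(">", nm), records[[nm]]), con)
  close(con)
  path
}

# the acceptance-scale dataset + screen, computed once and reused by
# several acceptance criteria (generation + HMMER + BLAST ~ a minute)
fix_acceptance <- function() {
  if (is.null(.fix$acc)) {
    plants <- rbind(
      plant_grid(families = c("accA", "accB"), reps = 5L),
      do.call(rbind, lapply(c("+", "-"), function(s)
        plant_spec(family = "accA", side = "both_sides", strand = s))),
      # numeric boundary plants: at each limit
      plant_spec(family = "accB", gap_bp = 50L),
      plant_spec(family = "accB", gap_bp = -20L),
      plant_spec(family = "accB", partner_len_aa = 50L),
      plant_spec(family = "accB", partner_len_aa = 150L),
      plant_spec(family = "accB", hit_len_aa = 30L),
      plant_spec(family = "accB", hit_len_aa = 200L))
    ds <- generate_dataset(20L, plants, seed = 20260901L)
    hmm <- file.path(tempdir(), "acc.hmm")
    lib <- build_profile_library(ds$families, hmm)
    screen <- screen_genomes(ds$genomes, lib, "TA")
    .fix$acc <- list(plants = plants, dataset = ds, library = lib,
                     screen = screen)
  }
  .fix$acc
}
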