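test_that("synth_gene emits valid deterministic genes", {
  g2 <- synth_gene(2L, seed = 1L)
  expect_equal(nchar(g2), 9L)
  expect_equal(substr(g2, 1, 3), "ATG")
  expect_true(substr(g2, 7, 9) %in% c("TAA", "TAG", "TGA"))
  expect_identical(synth_gene(50L, seed = 9L), synth_gene(50L, seed = 9L))
  expect_false(identical(synth_gene(50L, seed = 9L),
                         synth_gene(50L, seed = 10L)))
  for (s in 1:5) {
    g <- synth_gene(80L, seed = s)
    p <- operondetect:::translate_cds(g, first_to_met = FALSE,
                                      strip_stop = FALSE)
    expect_equal(substr(p, nchar(p), nchar(p)), "*")
    expect_false(grepl("\\*", substr(p, 1, nchar(p) - 1L)))
  }
})

test_that("make_family controls divergence and keeps alignment-ready lengths", {
  base <- synth_gene(60L, seed = 3L)
  same <- make_family(base, n_variants = 5L, sub_rate = 0, seed = 4L)
  expect_true(all(same$proteins == same$base_protein))
  fam <- make_family(base, n_variants = 10L, sub_rate = 0.1, seed = 4L)
  expect_equal(unique(nchar(fam$proteins)), 60L)
  expect_true(any(fam$proteins != fam$base_protein))
  # genes re-translate to their proteins
  retr <- vapply(fam$genes, operondetect:::translate_cds, character(1))
  expect_identical(unname(retr), unname(fam$proteins))
  expect_identical(make_family(base, 10L, 0.1, seed = 4L)$proteins,
                   fam$proteins)
  expect_error(make_family(base, 5L, 0.5, seed = 1L))
})

test_that("a family profile scores held-out members above 20 bits and
           unrelated proteins below", {
  lib <- fix_library()
  fam <- fix_family()
  held_out <- make_family(synth_gene(100L, seed = 4242L), n_variants = 25L,
                          sub_rate = 0.05, seed = 888L)
  orfs <- rbind(
    {
      o <- fake_orf(start = 1L, plen = 100L)
      o$protein <- unname(held_out$proteins[[25L]]); o
    },
    {
      o <- fake_orf(start = 900L, plen = 100L)
      o$protein <- operondetect:::translate_cds(synth_gene(100L,
                                                           seed = 5555L)); o
    })
  hits <- filter_by_score(run_profile_search(orfs, lib), 20)
  expect_true(orfs$orf_id[1] %in% hits$orf_id)
  expect_false(orfs$orf_id[2] %in% hits$orf_id)
})

test_that("plant_spec encodes violations one unit past each limit", {
  expect_equal(plant_spec(violation = "distance")$gap_bp, 51L)
  expect_equal(plant_spec(violation = "overlap")$gap_bp, -22L)
  expect_equal(plant_spec(violation = "partner_short")$partner_len_aa, 49L)
  expect_equal(plant_spec(violation = "partner_long")$partner_len_aa, 151L)
  expect_equal(plant_spec(violation = "hit_short")$hit_len_aa, 29L)
  expect_equal(plant_spec(violation = "hit_long")$hit_len_aa, 201L)
  expect_equal(plant_spec()$expected, "accepted")
  expect_equal(plant_spec(violation = "distance")$expected,
               "discarded:distance")
  expect_equal(plant_spec(gap_bp = 50L)$expected, "accepted")
  expect_equal(plant_spec(gap_bp = 51L)$expected, "discarded:distance")
  expect_equal(plant_spec(gap_bp = -20L)$expected, "accepted")
  expect_error(plant_spec(side = "both_sides", violation = "orphan"))
})

test_that("generate_dataset is byte-identical under a fixed seed and
           realises the planted geometry", {
  plants <- rbind(plant_spec(), plant_spec(violation = "distance"),
                  plant_spec(violation = "overlap", side = "upstream"),
                  plant_spec(violation = "ambiguous", strand = "-"),
                  plant_spec(side = "both_sides"))
  d1 <- generate_dataset(2L, plants, seed = 314L)
  d2 <- generate_dataset(2L, plants, seed = 314L)
  expect_identical(lapply(d1$genomes, `[[`, "contigs"),
                   lapply(d2$genomes, `[[`, "contigs"))
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(2L, plants, seed = 315L)
  expect_false(identical(lapply(d1$genomes, `[[`, "contigs"),
                         lapply(d3$genomes, `[[`, "contigs")))

  tr <- d1$truth
  contig_of <- function(gid)
    d1$genomes[[match(gid, vapply(d1$genomes, `[[`, "", "genome_id"))]]$contigs[[1]]
  # planted gap realised exactly (downstream plant, + strand)
  r <- tr[tr$violation == "distance", ]
  expect_equal(r$partner_down_start - r$hit_end - 1L, 51L)
  # overlap plant shares 22 bp
  r2 <- tr[tr$violation == "overlap", ]
  expect_equal(r2$hit_start - r2$partner_up_end - 1L, -22L)
  # ambiguous partner carries an 8+ N run in the genome sequence
  r3 <- tr[tr$violation == "ambiguous", ]
  pseq <- substr(contig_of(r3$genome_id), r3$partner_down_start,
                 r3$partner_down_end)
  expect_true(grepl("N{8,}", pseq))
  # both_sides plant has partners on both sides
  r4 <- tr[tr$side == "both_sides", ]
  expect_false(anyNA(c(r4$partner_up_start, r4$partner_down_start)))
})

test_that("every numeric constraint has realisable fixtures at the
           boundary and one unit past it", {
  specs <- list(plant_spec(gap_bp = 50L), plant_spec(gap_bp = 51L),
                plant_spec(gap_bp = -20L), plant_spec(gap_bp = -22L),
                plant_spec(partner_len_aa = 50L),
                plant_spec(partner_len_aa = 49L),
                plant_spec(partner_len_aa = 150L),
                plant_spec(partner_len_aa = 151L),
                plant_spec(hit_len_aa = 30L), plant_spec(hit_len_aa = 29L),
                plant_spec(hit_len_aa = 200L), plant_spec(hit_len_aa = 201L))
  plants <- do.call(rbind, specs)
  ds <- generate_dataset(3L, plants, seed = 2718L)
  expect_equal(nrow(ds$truth), nrow(plants))
  expect_identical(sort(unique(ds$truth$expected)),
                   sort(unique(plants$expected)))
  # a 21-bp same-strand overlap cannot exist: both genes would share a
  # codon-aligned frame and the hit's stop would sit inside the partner
  expect_error(generate_dataset(1L, plant_spec(gap_bp = -21L), seed = 1L),
               "unrealisable")
})

test_that("write_dataset emits FASTA, truth and GFF that read back", {
  plants <- rbind(plant_spec(), plant_spec(side = "upstream", strand = "-"))
  ds <- generate_dataset(1L, plants, seed = 99L)
  dir <- tempfile(); dir.create(dir)
  write_dataset(ds, dir, gff = TRUE)
  g <- read_genome_fasta(file.path(dir, "genome001.fasta"))
  expect_identical(unname(g$contigs), unname(ds$genomes[[1]]$contigs))
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), 2L)
  ann <- read_gff_cds(file.path(dir, "genome001.gff"), ds$genomes[[1]])
  # planted hit CDS appear in the annotation with matching coordinates
  expect_true(all(ds$truth$hit_start %in% ann$start |
                    ds$truth$hit_end %in% ann$end))
  merged <- merge_orf_sets(extract_orfs(ds$genomes[[1]]), ann)
  expect_true(all(ann$orf_id %in% merged$orf_id))
})
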