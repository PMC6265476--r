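ta <- load_preset("TA")$requirements

test_that("gene_gap computes intervening nucleotides with sign convention", {
  a <- fake_orf(start = 50L, plen = 15L); a$end <- 100L
  b1 <- fake_orf(start = 101L, plen = 20L)
  expect_equal(gene_gap(a, b1), 0L)                      # abutting
  b2 <- fake_orf(start = 151L, plen = 20L)
  expect_equal(gene_gap(a, b2), 50L)                     # TA distance limit
  b3 <- fake_orf(start = 80L, plen = 20L)
  expect_equal(gene_gap(a, b3), -21L)                    # past overlap limit
  b4 <- fake_orf(contig = "c2", start = 151L, plen = 20L)
  expect_error(gene_gap(a, b4), "different contigs")
})

test_that("has_ambiguous_run requires >= 8 consecutive N/X", {
  mk <- function(core) paste0("ATG", core, "TAA")
  expect_true(has_ambiguous_run(mk("NNNNNNNN")))
  expect_false(has_ambiguous_run(mk("NNNNNNN")))
  expect_false(has_ambiguous_run(mk("NNNNANNNN")))       # interrupted run
  expect_true(has_ambiguous_run(mk("NXnxNXnx")))          # mixed N/X, any case
  expect_true(has_ambiguous_run(mk("NNNNN"), run_len = 5L))
})

test_that("candidate_partners applies geometry, strand and ordering rules", {
  hit <- fake_orf(start = 1000L, plen = 100L)            # + strand, end 1302
  p_ok <- fake_orf(start = hit$end + 31L, plen = 90L)    # gap 30, downstream
  p_anti <- fake_orf(start = hit$end + 31L, plen = 90L, strand = "-")
  orfs <- rbind(hit, p_ok)
  cand <- candidate_partners(hit, orfs, ta)
  expect_named(cand, c("upstream", "downstream"))
  expect_equal(nrow(cand$downstream), 1L)
  expect_equal(cand$downstream$gap_bp, 30L)
  expect_equal(nrow(cand$upstream), 0L)

  # opposite strand: excluded (operonic premise), unless relaxed
  orfs2 <- rbind(hit, p_anti)
  expect_equal(nrow(candidate_partners(hit, orfs2, ta)$downstream), 0L)
  expect_equal(nrow(candidate_partners(hit, orfs2, ta,
                                       allow_antisense = TRUE)$downstream),
               1L)

  # two qualifying candidates ordered by |gap| (frame-shifted ORFs may
  # overlap each other; ranking only looks at the gap to the hit)
  p5 <- fake_orf(start = hit$end + 6L, plen = 60L)
  p40 <- fake_orf(start = hit$end + 41L, plen = 60L)
  ord <- candidate_partners(hit, rbind(hit, p40, p5), ta)$downstream
  expect_equal(ord$gap_bp, c(5L, 40L))

  # minus-strand hit: upstream = larger forward coordinates
  hitm <- fake_orf(start = 1000L, plen = 100L, strand = "-")
  pdn <- fake_orf(start = hitm$start - (3L * 91L) - 31L, plen = 90L,
                  strand = "-")
  candm <- candidate_partners(hitm, rbind(hitm, pdn), ta)
  expect_equal(nrow(candm$downstream), 1L)
  expect_equal(nrow(candm$upstream), 0L)
})

test_that("evaluate_hit accepts and discards per orientation with reasons", {
  hit <- fake_orf(start = 1000L, plen = 100L)
  p_dn <- fake_orf(start = hit$end + 31L, plen = 90L)
  p_up <- fake_orf(start = hit$start - 3L * 91L - 21L, plen = 90L)

  v <- evaluate_hit(hit, rbind(hit, p_dn), ta)
  expect_equal(v$status, "accepted")
  expect_equal(nrow(v$partners), 1L)
  expect_equal(v$partners$side, "downstream")

  # hit length outside 30-200 aa
  big <- fake_orf(start = 1000L, plen = 250L)
  v2 <- evaluate_hit(big, rbind(big, p_dn), ta)
  expect_equal(v2$reason, "hit_length")

  # nothing within reach
  v3 <- evaluate_hit(hit, hit, ta)
  expect_equal(v3$reason, "no_partner")

  # either with both sides qualifying: both partners attached
  v4 <- evaluate_hit(hit, rbind(hit, p_dn, p_up), ta)
  expect_equal(v4$status, "accepted")
  expect_equal(sort(v4$partners$side), c("downstream", "upstream"))

  # orientation = both requires both sides
  both <- merge_requirements(ta, list(orientation = "both"))
  expect_equal(evaluate_hit(hit, rbind(hit, p_dn), both)$status, "discarded")
  expect_equal(evaluate_hit(hit, rbind(hit, p_dn, p_up), both)$status,
               "accepted")

  # orientation = upstream ignores downstream candidates
  upo <- merge_requirements(ta, list(orientation = "upstream"))
  expect_equal(evaluate_hit(hit, rbind(hit, p_dn), upo)$reason, "no_partner")
})

test_that("discard reasons follow the near-miss precedence", {
  hit <- fake_orf(start = 1000L, plen = 100L)
  gap_at <- function(gap, plen = 90L, nt = NULL) {
    o <- fake_orf(start = hit$end + gap + 1L, plen = plen)
    if (!is.null(nt)) o$nt_seq <- nt
    o
  }
  # distance: gap one past the limit
  expect_equal(evaluate_hit(hit, rbind(hit, gap_at(51L)), ta)$reason,
               "distance")
  # overlap: one past the overlap limit
  expect_equal(evaluate_hit(hit, rbind(hit, gap_at(-21L)), ta)$reason,
               "overlap")
  # partner length
  expect_equal(evaluate_hit(hit, rbind(hit, gap_at(30L, plen = 49L)),
                            ta)$reason, "partner_length")
  # ambiguous beats everything
  amb <- gap_at(30L, nt = paste0("ATG", strrep("N", 12),
                                 strrep("A", 3L * 91L - 18L), "TAA"))
  expect_equal(evaluate_hit(hit, rbind(hit, amb), ta)$reason, "ambiguous")
  # a far-away ORF is not a near-miss: reason stays no_partner
  expect_equal(evaluate_hit(hit, rbind(hit, gap_at(5000L)), ta)$reason,
               "no_partner")
})

test_that("filter_operons partitions hits and the oracle agrees", {
  acc <- fix_acceptance()
  screen <- acc$screen
  expect_equal(nrow(screen$operons) + nrow(screen$discarded),
               nrow(screen$hits))
  # exhaustive independent re-evaluation of every hit
  req <- screen$params$requirements
  for (i in seq_len(nrow(screen$hits))) {
    hid <- screen$hits$orf_id[i]
    hrow <- screen$orfs[screen$orfs$orf_id == hid, ]
    want <- oracle_verdict(hrow, screen$orfs, req)
    got <- if (hid %in% screen$operons$hit_orf_id) "accepted" else "rejected"
    if (want == "hit_length")
      want <- "rejected"
    expect_equal(got, want, info = hid)
  }
})

test_that("accepted partners satisfy all constraints; tightening is monotone", {
  acc <- fix_acceptance()
  ops <- acc$screen$operons
  for (side in c("up", "down")) {
    gap <- ops[[paste0("partner_", side, "_gap_bp")]]
    prot <- ops[[paste0("partner_", side, "_protein")]]
    sel <- !is.na(gap)
    expect_true(all(gap[sel] >= -ta$max_overlap_bp))
    expect_true(all(gap[sel] <= ta$max_distance_bp))
    expect_true(all(nchar(prot[sel]) >= 50L & nchar(prot[sel]) <= 150L))
  }
  # monotonicity sweep: tightening any constraint never grows the accepted set
  hits <- acc$screen$hits
  orfs <- acc$screen$orfs
  base_n <- nrow(filter_operons(hits, orfs, ta)$operons)
  sweeps <- list(list(max_distance_bp = 20L), list(max_overlap_bp = 0L),
                 list(hit_min_aa = 90L), list(hit_max_aa = 110L),
                 list(partner_min_aa_up = 80L, partner_min_aa_down = 80L),
                 list(partner_max_aa_up = 100L, partner_max_aa_down = 100L))
  for (ov in sweeps) {
    tight <- merge_requirements(ta, ov)
    expect_lte(nrow(filter_operons(hits, orfs, tight)$operons), base_n)
  }
})
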