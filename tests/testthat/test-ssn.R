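edge <- function(a, b, ev, id) {
  data.frame(seq_a = a, seq_b = b, evalue = ev, identity_pct = id,
             stringsAsFactors = FALSE)
}

test_that("build_ssn enforces the e-value 0.01 / identity 30% boundaries", {
  ids <- c("s1", "s2", "s3", "s4")
  edges <- rbind(
    edge("s1", "s2", 1e-30, 29.9),   # identity below 30: dropped
    edge("s1", "s3", 0.02, 95),      # e-value above 0.01: dropped
    edge("s2", "s3", 0.01, 30))      # both at the limit: kept
  g <- build_ssn(ids, edges)
  expect_equal(igraph::ecount(g), 1L)
  comp <- ssn_components(g, role = "hit")
  expect_equal(comp$cluster[comp$seq_id == "s2"],
               comp$cluster[comp$seq_id == "s3"])
  expect_false(comp$cluster[comp$seq_id == "s1"] %in%
                 comp$cluster[comp$seq_id %in% c("s2", "s3")])
  # no edges at all: every node its own component
  g0 <- build_ssn(ids, edges[0, ])
  expect_equal(length(unique(ssn_components(g0)$cluster)), 4L)
})

test_that("connected components are single-linkage transitive and labelled
           by size then lexicographic member", {
  ids <- c("a", "b", "c", "x", "y", "z", "q")
  edges <- rbind(edge("a", "b", 1e-5, 90), edge("b", "c", 1e-5, 90),
                 edge("x", "y", 1e-5, 90), edge("y", "z", 1e-5, 90))
  comp <- ssn_components(build_ssn(ids, edges), role = "hit")
  lab <- function(s) comp$cluster[comp$seq_id == s]
  # chain a-b-c: one cluster without an a-c edge
  expect_equal(lab("a"), lab("c"))
  # two size-3 clusters: tie broken by smallest member -> {a,b,c} gets "a"
  expect_equal(lab("a"), "a")
  expect_equal(lab("x"), "b")
  expect_equal(lab("q"), "c")
  # upper-case labels for partner roles
  compU <- ssn_components(build_ssn(ids, edges), role = "partner_pooled")
  expect_equal(compU$cluster[compU$seq_id == "a"], "A")
  # label scheme continues past 26 components
  expect_equal(operondetect:::cluster_label(26L, "upper"), "Z")
  expect_equal(operondetect:::cluster_label(27L, "upper"), "A1")
  expect_equal(operondetect:::cluster_label(53L, "upper"), "A2")
})

test_that("components match brute-force transitive closure on random graphs", {
  for (i in 1:10) {
    n <- 5L + (i %% 11L)
    nodes <- sprintf("n%02d", seq_len(n))
    withr::with_seed(5100L + i, {
      m <- matrix(stats::runif(n * n) < 0.15, n, n)
      pairs <- which(m & upper.tri(m), arr.ind = TRUE)
    })
    ep <- cbind(nodes[pairs[, 1]], nodes[pairs[, 2]])
    edges <- if (nrow(ep)) {
      data.frame(seq_a = ep[, 1], seq_b = ep[, 2], evalue = 1e-9,
                 identity_pct = 99, stringsAsFactors = FALSE)
    } else edge("x", "y", 1, 0)[0, ]
    comp <- ssn_components(build_ssn(nodes, edges))
    got <- unname(lapply(split(comp$seq_id, comp$cluster), sort))
    want <- unname(lapply(oracle_components(nodes, ep), sort))
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("labelling is invariant under input permutation and thresholds
           only refine the partition", {
  ids <- sprintf("s%02d", 1:12)
  edges <- rbind(edge("s01", "s02", 1e-6, 80), edge("s02", "s03", 1e-3, 45),
                 edge("s04", "s05", 1e-6, 35), edge("s06", "s07", 5e-3, 31),
                 edge("s08", "s09", 1e-9, 99))
  comp1 <- ssn_components(build_ssn(ids, edges))
  withr::with_seed(1L, perm <- sample(ids))
  comp2 <- ssn_components(build_ssn(perm, edges[sample(nrow(edges)), ]))
  expect_identical(comp1, comp2[match(comp1$seq_id, comp2$seq_id), ] |>
                     (\(d) { rownames(d) <- NULL; d })())
  # stricter thresholds only split, never merge
  strict <- ssn_components(build_ssn(ids, edges, max_evalue = 1e-4,
                                     min_identity = 40))
  for (cl in unique(strict$cluster)) {
    members <- strict$seq_id[strict$cluster == cl]
    expect_equal(length(unique(comp1$cluster[comp1$seq_id %in% members])), 1L)
  }
})

test_that("pairwise_similarity reports identity and excludes self-hits", {
  fam <- fix_family()
  seqs <- c(dup1 = unname(fam$proteins[[1]]), dup2 = unname(fam$proteins[[1]]),
            rnd = operondetect:::translate_cds(synth_gene(100L, seed = 31L)))
  edges <- pairwise_similarity(seqs)
  expect_false(any(edges$seq_a == edges$seq_b))
  pair <- edges[edges$seq_a == "dup1" & edges$seq_b == "dup2", ]
  expect_equal(nrow(pair), 1L)
  expect_equal(pair$identity_pct, 100)
  # unrelated sequence ends up in its own cluster at the thresholds
  assign <- cluster_sequences(seqs, role = "hit")
  expect_equal(assign$cluster[assign$seq_id == "dup1"],
               assign$cluster[assign$seq_id == "dup2"])
  expect_false(assign$cluster[assign$seq_id == "rnd"] ==
                 assign$cluster[assign$seq_id == "dup1"])
  # single sequence: one singleton cluster, no self-edge
  one <- cluster_sequences(seqs[1], role = "hit")
  expect_equal(nrow(one), 1L)
})

test_that("partner networks pool for 'either' and split for 'both'", {
  acc <- fix_acceptance()
  ops <- acc$screen$operons
  pooled <- partition_partner_networks(ops, "either")
  expect_named(pooled, "partner_pooled")
  n_up <- sum(!is.na(ops$partner_up_orf_id))
  n_dn <- sum(!is.na(ops$partner_down_orf_id))
  expect_equal(length(pooled$partner_pooled), n_up + n_dn)
  both <- partition_partner_networks(ops, "both")
  expect_named(both, c("partner_up", "partner_down"))
  expect_equal(length(both$partner_up), n_up)
  expect_equal(length(both$partner_down), n_dn)
  # empty operon set: empty network
  expect_equal(length(partition_partner_networks(ops[0, ],
                                                 "either")$partner_pooled),
               0L)
})

test_that("label_operons builds partner-hit type labels", {
  ops <- rbind(
    data.frame(hit_orf_id = "h1", partner_up_orf_id = NA_character_,
               partner_down_orf_id = "p1", stringsAsFactors = FALSE),
    data.frame(hit_orf_id = "h2", partner_up_orf_id = NA_character_,
               partner_down_orf_id = "p2", stringsAsFactors = FALSE))
  hit_assign <- data.frame(seq_id = c("h1", "h2"), cluster = c("a", "a"),
                           role = "hit", stringsAsFactors = FALSE)
  part <- list(partner_pooled = data.frame(
    seq_id = c("p1", "p2"), cluster = c("A", "B"), role = "partner_pooled",
    stringsAsFactors = FALSE))
  lab <- label_operons(ops, hit_assign, part)
  expect_equal(lab$operon_type, c("A-a", "B-a"))  # same hit, two types
  # unassigned sequence is an internal consistency error
  bad <- ops; bad$partner_down_orf_id[1] <- "missing"
  expect_error(label_operons(bad, hit_assign, part), "consistency")
})

test_that("map_discarded maps to accepted clusters or fresh X labels", {
  fam <- fix_family()
  accepted <- c(acc1 = unname(fam$proteins[[1]]),
                acc2 = unname(fam$proteins[[2]]))
  hit_assign <- cluster_sequences(accepted, role = "hit")
  # one discarded related to the accepted family, one unrelated
  related <- unname(fam$proteins[[3]])
  unrelated <- operondetect:::translate_cds(synth_gene(120L, seed = 87L))
  disc <- c(d_rel = related, d_un = unrelated)
  m <- map_discarded(disc, accepted, hit_assign)
  acc_cl <- unique(hit_assign$cluster)
  expect_equal(m$cluster[m$seq_id == "d_rel"],
               paste0(acc_cl, "_discarded"))
  expect_match(m$cluster[m$seq_id == "d_un"], "^X1_discarded$")
  # no discarded hits: empty assignment
  expect_equal(nrow(map_discarded(character(0), accepted, hit_assign)), 0L)
})
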